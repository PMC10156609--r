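# Read prefiltering: drop ambiguous reads, then subtract everything that a
# linear end-to-end alignment to the transcriptome or genome can explain.
# Lariat-spanning reads traverse the junction in inverted order, so no
# linear reference contains them (unless the lariat loop is shorter than the
# read), and they survive this subtraction.

#' Load single-end reads from FASTQ
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return data.frame with `read_id` and `seq` (uppercased).
#' @export
load_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             seq = toupper(as.character(ss)))
}

#' Remove reads with too many ambiguous bases
#'
#' Keeps reads whose fraction of non-A/C/G/T bases is strictly below
#' `max_frac` (a read with exactly 5\% ambiguous bases is removed at the
#' default).
#'
#' @param reads data.frame with a `seq` column.
#' @param max_frac maximum tolerated ambiguous fraction (default 0.05).
#' @return the filtered data.frame; the number removed is attached as the
#'   `n_removed` attribute.
#' @export
filter_ambiguous <- function(reads, max_frac = 0.05) {
  if (!nrow(reads)) return(reads)
  amb <- stringi::stri_count_charclass(reads$seq, "[^ACGT]")
  frac <- amb / nchar(reads$seq)
  out <- reads[frac < max_frac, , drop = FALSE]
  attr(out, "n_removed") <- nrow(reads) - nrow(out)
  rownames(out) <- NULL
  out
}

# Which reads (constant length L) align end-to-end to any sequence of `refs`
# with at most `budget` mismatches and no indels? Pigeonhole over budget+1
# disjoint 20-nt trusted bands: an alignment with <= budget mismatches
# leaves at least one band exact, so the union of per-band searches is
# complete. Reads containing N are never matched (ambiguous bases do not
# pair with the reference).
which_linear_hits <- function(seqs, refs, budget) {
  L <- nchar(seqs[1])
  clean <- !grepl("N", seqs, fixed = TRUE)
  hit <- logical(length(seqs))
  if (!any(clean)) return(hit)
  idx <- which(clean)
  pats <- Biostrings::DNAStringSet(seqs[idx])
  bands <- if (budget == 0L) list(c(1L, L)) else {
    k <- budget + 1L
    if (L < 20L * k) stop("reads too short for the mismatch budget")
    starts <- as.integer(round(seq(1L, L - 19L, length.out = k)))
    lapply(starts, function(s) c(s, 20L))
  }
  for (b in bands) {
    pd <- if (budget == 0L) Biostrings::PDict(pats)
          else Biostrings::PDict(pats, tb.start = b[1], tb.width = b[2])
    for (r in seq_along(refs)) {
      got <- Biostrings::whichPDict(pd, refs[[r]], max.mismatch = budget)
      hit[idx[got]] <- TRUE
    }
    if (all(hit[idx])) break
  }
  hit
}

#' Subtract linearly mappable reads
#'
#' Discards any read with an end-to-end, no-indel alignment (on either
#' strand) to the transcriptome or the genome with at most
#' `floor(mismatch_rate * read_length)` mismatches. What survives is the
#' lariat-search set. The matcher is a built-in exact/trusted-band search
#' satisfying this alignment contract; the mismatch rate is exposed so the
#' stringency can be tuned.
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param genome genome object.
#' @param transcriptome optional named character vector of spliced
#'   transcript sequences (see [transcript_sequences()]); checked first.
#' @param mismatch_rate per-base mismatch budget (default 0.0133, a
#'   conservative translation of a linear aligner's score floor).
#' @return the surviving reads; attributes `n_tx_removed` and
#'   `n_genome_removed` carry per-stage counts.
#' @export
subtract_mapped <- function(reads, genome, transcriptome = NULL,
                            mismatch_rate = 0.0133) {
  if (!nrow(reads)) return(reads)
  mk_refs <- function(x) {
    ss <- Biostrings::DNAStringSet(unclass(x))
    c(ss, Biostrings::reverseComplement(ss))
  }
  tx_refs <- if (length(transcriptome)) mk_refs(transcriptome) else NULL
  g_refs <- mk_refs(genome)
  tx_hit <- g_hit <- logical(nrow(reads))
  for (L in unique(nchar(reads$seq))) {
    sel <- which(nchar(reads$seq) == L)
    budget <- floor(mismatch_rate * L)
    if (!is.null(tx_refs))
      tx_hit[sel] <- which_linear_hits(reads$seq[sel], tx_refs, budget)
    g_hit[sel] <- which_linear_hits(reads$seq[sel], g_refs, budget)
  }
  out <- reads[!(tx_hit | g_hit), , drop = FALSE]
  attr(out, "n_tx_removed") <- sum(tx_hit)
  attr(out, "n_genome_removed") <- sum(g_hit & !tx_hit)
  rownames(out) <- NULL
  out
}
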