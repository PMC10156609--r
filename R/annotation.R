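#' Load a transcript annotation (GTF or BED12)
#'
#' Parses a transcript annotation into an exon table, the package's working
#' representation: one row per exon per transcript, 1-based closed
#' coordinates, with `exon_rank` numbering exons in transcription order.
#'
#' GTF files must carry `gene_id` and `transcript_id` attributes on their
#' `exon` features. BED12 files contribute one transcript per line; the
#' `name` field is used as `gene_id|transcript_id` when it contains a pipe,
#' otherwise as both.
#'
#' @param path path to a `.gtf`/`.gff` or `.bed` file.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, `exon_rank`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  if (!is.null(gr$blocks)) {                      # BED12: expand blocks
    nm <- as.character(gr$name)
    gid <- ifelse(grepl("|", nm, fixed = TRUE), sub("\\|.*$", "", nm), nm)
    tid <- ifelse(grepl("|", nm, fixed = TRUE), sub("^.*\\|", "", nm), nm)
    ex <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      data.frame(contig = as.character(GenomicRanges::seqnames(gr)[i]),
                 start = GenomicRanges::start(gr)[i] + IRanges::start(b) - 1L,
                 end   = GenomicRanges::start(gr)[i] + IRanges::end(b) - 1L,
                 strand = as.character(GenomicRanges::strand(gr)[i]),
                 gene_id = gid[i], transcript_id = tid[i])
    }))
  } else {
    keep <- if (!is.null(gr$type)) gr$type == "exon" else rep(TRUE, length(gr))
    gr <- gr[keep]
    if (is.null(gr$gene_id) || is.null(gr$transcript_id))
      stop("GTF exons must carry gene_id and transcript_id attributes")
    ex <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     gene_id = as.character(gr$gene_id),
                     transcript_id = as.character(gr$transcript_id))
  }
  validate_exons(ex)
}

# Order, rank and sanity-check an exon table.
validate_exons <- function(ex) {
  if (!all(ex$strand %in% c("+", "-"))) stop("exon strand must be + or -")
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (idx in sp) {
    if (length(unique(ex$contig[idx])) > 1L)
      stop("transcript spans contigs: ", ex$transcript_id[idx[1]])
    if (length(unique(ex$strand[idx])) > 1L)
      stop("transcript mixes strands: ", ex$transcript_id[idx[1]])
    if (length(idx) > 1L &&
        any(ex$start[idx][-1] <= ex$end[idx][-length(idx)]))
      stop("overlapping exons within transcript: ", ex$transcript_id[idx[1]])
  }
  rank <- unlist(lapply(sp, function(idx) {
    r <- seq_along(idx)
    if (ex$strand[idx[1]] == "-") r <- rev(r)
    r
  }), use.names = FALSE)
  ex$exon_rank <- NA_integer_
  ex$exon_rank[unlist(sp, use.names = FALSE)] <- rank
  rownames(ex) <- NULL
  ex
}

#' Derive introns from an exon table
#'
#' Introns are the gaps between consecutive exons of each transcript. The
#' splice-site coordinates follow transcription order: `five_prime_ss` is the
#' first intronic base (the G of the canonical GT) and `three_prime_ss` the
#' last intronic base (the G of the canonical AG).
#'
#' @param exons exon table from [load_annotation()].
#' @return data.frame of introns with columns `contig`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`, `five_prime_ss`,
#'   `three_prime_ss`, `length`.
#' @export
derive_introns <- function(exons) {
  sp <- split(exons, exons$transcript_id)
  out <- lapply(sp, function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    s <- ex$end[-nrow(ex)] + 1L
    e <- ex$start[-1L] - 1L
    data.frame(contig = ex$contig[1], start = s, end = e,
               strand = ex$strand[1], gene_id = ex$gene_id[1],
               transcript_id = ex$transcript_id[1])
  })
  ir <- do.call(rbind, out)
  if (is.null(ir)) {
    ir <- data.frame(contig = character(), start = integer(), end = integer(),
                     strand = character(), gene_id = character(),
                     transcript_id = character())
  }
  ir$five_prime_ss  <- ifelse(ir$strand == "+", ir$start, ir$end)
  ir$three_prime_ss <- ifelse(ir$strand == "+", ir$end, ir$start)
  ir$length <- ir$end - ir$start + 1L
  rownames(ir) <- NULL
  ir
}

#' Constitutive introns of each gene
#'
#' An intron is constitutive when its exact interval appears as an intron in
#' every transcript of its parent gene. These are the introns searched for
#' recursive splice sites.
#'
#' @param exons exon table.
#' @return data.frame of unique introns with `intron_id` and
#'   `constitutive = TRUE`.
#' @export
constitutive_introns <- function(exons) {
  ir <- derive_introns(exons)
  n_tx <- tapply(exons$transcript_id, exons$gene_id,
                 function(x) length(unique(x)))
  key <- paste(ir$gene_id, ir$contig, ir$start, ir$end, ir$strand, sep = ":")
  cnt <- tapply(ir$transcript_id, key, function(x) length(unique(x)))
  uniq <- ir[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  keep <- cnt[ukey] == n_tx[uniq$gene_id]
  out <- uniq[keep, setdiff(names(uniq), "transcript_id"), drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out$constitutive <- rep(TRUE, nrow(out))
  out$intron_id <- sprintf("%s:%s:%d-%d:%s", out$gene_id, out$contig,
                           out$start, out$end, out$strand)
  rownames(out) <- NULL
  out
}

#' Internal cassette exons
#'
#' Flags each distinct exon interval as internal (neither first nor last in
#' any transcript containing it, across all genes sharing it) and as cassette
#' (absent from at least one transcript of its gene while present in
#' another). Internal cassette exons are the substrate of the distal-exonic
#' recursive-splicing mode.
#'
#' @param exons exon table.
#' @return data.frame of unique exons with `is_internal` and `is_cassette`.
#' @export
internal_cassette_exons <- function(exons) {
  sp <- split(exons, exons$transcript_id)
  # terminal = first or last exon of its transcript (by rank)
  term <- unlist(lapply(sp, function(ex) {
    ex$exon_rank %in% range(ex$exon_rank)
  }), use.names = FALSE)
  ord <- order(exons$transcript_id, exons$start)
  terminal <- logical(nrow(exons))
  terminal[ord] <- term
  key <- paste(exons$contig, exons$start, exons$end, exons$strand, sep = ":")
  internal_by_key <- tapply(!terminal, key, all)
  uniq <- exons[!duplicated(key), c("contig", "start", "end", "strand",
                                    "gene_id"), drop = FALSE]
  ukey <- key[!duplicated(key)]
  uniq$is_internal <- as.logical(internal_by_key[ukey])
  n_tx_gene <- tapply(exons$transcript_id, exons$gene_id,
                      function(x) length(unique(x)))
  n_tx_exon <- tapply(exons$transcript_id, key, function(x) length(unique(x)))
  uniq$is_cassette <- as.integer(n_tx_exon[ukey]) < n_tx_gene[uniq$gene_id]
  uniq <- uniq[order(uniq$contig, uniq$start), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

#' Spliced transcript sequences
#'
#' Concatenates each transcript's exon sequences in transcription order.
#' These form the transcriptome reference used to subtract linear reads
#' before lariat mapping.
#'
#' @param genome genome object.
#' @param exons exon table.
#' @return named character vector, one sequence per transcript.
#' @export
transcript_sequences <- function(genome, exons) {
  sp <- split(exons, exons$transcript_id)
  vapply(sp, function(ex) {
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    paste(fetch_seq(genome, ex$contig, ex$start, ex$end, ex$strand),
          collapse = "")
  }, character(1))
}

#' Annotated splice-site coordinates
#'
#' One row per distinct (position, type) splice site across all introns of
#' the annotation. Positions are the first (5'ss) and last (3'ss) intronic
#' base in transcription order.
#'
#' @param introns intron table (any of the intron-producing functions).
#' @return data.frame with `contig`, `pos`, `strand`, `type` (`"5ss"` or
#'   `"3ss"`), `gene_id`.
#' @export
annotated_splice_sites <- function(introns) {
  ss <- rbind(
    data.frame(contig = introns$contig, pos = introns$five_prime_ss,
               strand = introns$strand, type = "5ss",
               gene_id = introns$gene_id),
    data.frame(contig = introns$contig, pos = introns$three_prime_ss,
               strand = introns$strand, type = "3ss",
               gene_id = introns$gene_id))
  ss[!duplicated(ss[c("contig", "pos", "strand", "type")]), , drop = FALSE]
}

#' Dump an interval table as BED6
#'
#' Converts the package's 1-based closed intervals to BED's 0-based half-open
#' convention at the boundary.
#'
#' @param df data.frame with `contig`, `start`, `end`, `strand` and
#'   optionally a `name` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  nm <- if ("name" %in% names(df)) df$name else
    if ("intron_id" %in% names(df)) df$intron_id else "."
  bed <- data.frame(df$contig, df$start - 1L, df$end, nm, 0L, df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
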