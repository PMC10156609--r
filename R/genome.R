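#' Load a genome from FASTA
#'
#' Reads every record of a FASTA file into memory as a named character vector
#' (one element per contig), uppercased and restricted to the A/C/G/T/N
#' alphabet. All coordinates in the package are 1-based, closed intervals on
#' the forward strand, following the Bioconductor convention; BED output is
#' converted at the boundary.
#'
#' @param path path to a FASTA file.
#' @return named character vector of contig sequences (class `rs_genome`).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate contig names in ", path)
  g <- toupper(as.character(ss))
  names(g) <- nm
  as_genome(g)
}

#' Coerce a named character vector to a genome object
#'
#' @param x named character vector of contig sequences.
#' @return the validated genome (class `rs_genome`).
#' @export
as_genome <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("contigs must be named")
  if (anyDuplicated(names(x))) stop("duplicate contig names")
  x <- toupper(x)
  bad <- stringi::stri_count_charclass(x, "[^ACGTN]") > 0
  if (any(bad)) {
    stop("non-ACGTN characters in contig(s): ",
         paste(names(x)[bad], collapse = ", "))
  }
  structure(x, class = c("rs_genome", "character"))
}

#' Fetch strand-correct genomic sequence
#'
#' Returns the sequence of `[start, end]` (1-based, closed) on `contig`; for
#' the minus strand the reverse complement is returned, so the result always
#' reads in transcription order for a feature on `strand`.
#'
#' @param genome genome from [load_genome()] or [as_genome()].
#' @param contig contig name.
#' @param start,end 1-based closed interval (vectorised).
#' @param strand `"+"` or `"-"` (vectorised).
#' @return character vector of sequences.
#' @export
fetch_seq <- function(genome, contig, start, end, strand = "+") {
  if (any(!contig %in% names(genome))) {
    stop("unknown contig(s): ",
         paste(setdiff(unique(contig), names(genome)), collapse = ", "))
  }
  n <- max(length(contig), length(start), length(end), length(strand))
  contig <- rep_len(contig, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  if (any(start < 1L) || any(end > nchar(genome)[match(contig, names(genome))]))
    stop("interval outside contig bounds")
  if (any(end < start)) stop("end < start")
  s <- stringi::stri_sub(unname(genome[contig]), start, end)
  neg <- strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

#' Write a genome to FASTA
#'
#' @param genome genome object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
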