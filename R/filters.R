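# Individual filter predicates of the cascade. Each is a pure, vectorised
# predicate (keep = TRUE) so the cascade can apply them in any order and
# report per-stage survivor counts; the final surviving set is
# order-independent.

#' Branchpoint-distance filter
#'
#' Keeps lariat reads whose branchpoint lies between `min` and `max` nt
#' (inclusive) upstream of the 3' splice site, the empirically constrained
#' range for U2 branchpoints.
#'
#' @param bp_to_3ss integer vector: tail length downstream of (not
#'   including) the branchpoint.
#' @param min,max inclusive bounds (defaults 10 and 60).
#' @return logical keep vector.
#' @export
filter_bp_distance <- function(bp_to_3ss, min = 10L, max = 60L) {
  bp_to_3ss >= min & bp_to_3ss <= max
}

#' Self-primed-artifact filter
#'
#' A library-preparation artifact can circularise a linear fragment where
#' two short identical sequences allowed intramolecular priming, mimicking a
#' lariat junction. Such events are recognisable because the `k` nt of
#' reference sequence up to and including the inferred branchpoint equal the
#' `k` nt immediately upstream of the 5' splice site; exact matches are
#' dropped. Reads whose 5'ss lies within `k` nt of the contig start cannot
#' be checked and are kept with a warning.
#'
#' @param lariats lariat table (needs `contig`, `strand`, `five_pos`,
#'   `bp_pos`).
#' @param genome genome object.
#' @param k comparison length in nt (default 5).
#' @return logical keep vector.
#' @export
filter_self_primed <- function(lariats, genome, k = 5L) {
  n <- nrow(lariats)
  if (!n) return(logical())
  clen <- nchar(genome)[match(lariats$contig, names(genome))]
  pos <- lariats$strand == "+"
  bp_s <- ifelse(pos, lariats$bp_pos - k + 1L, lariats$bp_pos)
  bp_e <- ifelse(pos, lariats$bp_pos, lariats$bp_pos + k - 1L)
  up_s <- ifelse(pos, lariats$five_pos - k, lariats$five_pos + 1L)
  up_e <- ifelse(pos, lariats$five_pos - 1L, lariats$five_pos + k)
  ok <- bp_s >= 1L & up_s >= 1L & bp_e <= clen & up_e <= clen
  keep <- rep(TRUE, n)
  if (any(!ok)) {
    warning(sum(!ok), " lariat read(s) too close to a contig edge for the ",
            "self-primed check; kept")
  }
  if (any(ok)) {
    bp5 <- fetch_seq(genome, lariats$contig[ok], bp_s[ok], bp_e[ok],
                     lariats$strand[ok])
    up5 <- fetch_seq(genome, lariats$contig[ok], up_s[ok], up_e[ok],
                     lariats$strand[ok])
    keep[ok] <- bp5 != up5
  }
  keep
}

#' Proximity-to-annotated-splice-site filter
#'
#' Drops junctions whose recursive (or decoy) site lies within `window` nt
#' of an annotated splice site of the same type on the same strand — a
#' heuristic against cryptic alternative 5'/3' splice sites. A junction is
#' dropped if either of its non-annotated ends is proximal.
#'
#' @param junction_like table with `contig`, `strand`, `five_class`,
#'   `five_pos`, `three_class`, `three_pos` (lariat or junction rows).
#' @param annotated_ss table from [annotated_splice_sites()].
#' @param window inclusive distance in nt (default 100; a site exactly
#'   `window` away is dropped).
#' @return logical keep vector.
#' @export
filter_proximity <- function(junction_like, annotated_ss, window = 100L) {
  n <- nrow(junction_like)
  if (!n) return(logical())
  near <- function(pos, contig, strand, type) {
    ann <- annotated_ss[annotated_ss$type == type, , drop = FALSE]
    if (!nrow(ann)) return(rep(FALSE, length(pos)))
    ann_gr <- GenomicRanges::GRanges(
      ann$contig,
      IRanges::IRanges(ann$pos - window, ann$pos + window), ann$strand)
    q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos), strand)
    overlaps_any_union(q, ann_gr)
  }
  drop <- rep(FALSE, n)
  f5 <- junction_like$five_class != "annotated"
  if (any(f5)) {
    drop[f5] <- near(junction_like$five_pos[f5], junction_like$contig[f5],
                     junction_like$strand[f5], "5ss")
  }
  t3 <- junction_like$three_class != "annotated"
  if (any(t3)) {
    drop[t3] <- drop[t3] | near(junction_like$three_pos[t3],
                                junction_like$contig[t3],
                                junction_like$strand[t3], "3ss")
  }
  !drop
}

#' Repeat / low-complexity filter
#'
#' Drops lariat reads when the 20-nt minimum mapped region at either end of
#' the alignment — downstream of and including the 5' splice site, or
#' upstream of and including the branchpoint (transcription order) —
#' overlaps a simple repeat or low-complexity interval by at least one base.
#'
#' @param lariats lariat table.
#' @param repeats data.frame with `contig`, `start`, `end` (1-based closed)
#'   and optionally `class`; rows whose class is not `"Simple_repeat"` or
#'   `"Low_complexity"` are ignored.
#' @param flank window size in nt (default 20, the minimum mapped region).
#' @return logical keep vector.
#' @export
filter_repeats <- function(lariats, repeats, flank = 20L) {
  n <- nrow(lariats)
  if (!n) return(logical())
  if (is.null(repeats) || !nrow(repeats)) return(rep(TRUE, n))
  if (!is.null(repeats$class)) {
    repeats <- repeats[repeats$class %in% c("Simple_repeat",
                                            "Low_complexity"), , drop = FALSE]
    if (!nrow(repeats)) return(rep(TRUE, n))
  }
  rep_gr <- GenomicRanges::GRanges(repeats$contig,
                                   IRanges::IRanges(repeats$start,
                                                    repeats$end))
  pos <- lariats$strand == "+"
  w5 <- GenomicRanges::GRanges(
    lariats$contig,
    IRanges::IRanges(ifelse(pos, lariats$five_pos,
                            lariats$five_pos - flank + 1L),
                     ifelse(pos, lariats$five_pos + flank - 1L,
                            lariats$five_pos)))
  wbp <- GenomicRanges::GRanges(
    lariats$contig,
    IRanges::IRanges(ifelse(pos, lariats$bp_pos - flank + 1L,
                            lariats$bp_pos),
                     ifelse(pos, lariats$bp_pos,
                            lariats$bp_pos + flank - 1L)))
  !(overlaps_any_union(w5, rep_gr) | overlaps_any_union(wbp, rep_gr))
}

#' Exon-body branchpoint filter (distal mode)
#'
#' For distal-exonic junctions the branchpoint must fall strictly inside the
#' exon: within the exon coordinates but neither its first nor its last base
#' (strand-aware in the sense that first/last refer to genomic bounds; both
#' are excluded, so the rule is symmetric).
#'
#' @param lariats lariat table with `exon_start`/`exon_end` columns.
#' @return logical keep vector.
#' @export
filter_exonic_bp <- function(lariats) {
  lariats$bp_pos > lariats$exon_start & lariats$bp_pos < lariats$exon_end
}

# overlapsAny after harmonising seqlevels (queries and subjects may each
# mention contigs the other never touches).
overlaps_any_union <- function(q, s) {
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  IRanges::overlapsAny(q, s)
}

# Count occurrences of each k-mer in the genome, both strands, overlapping
# matches included. Used by the high-confidence uniqueness criterion.
genome_kmer_count <- function(genome, kmers) {
  u <- unique(kmers)
  cnt <- vapply(u, function(k) {
    sum(stringi::stri_count_fixed(unclass(genome), k, overlap = TRUE)) +
      sum(stringi::stri_count_fixed(unclass(genome), revcomp(k),
                                    overlap = TRUE))
  }, numeric(1))
  cnt[kmers]
}
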