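# Split-read lariat mapping.
#
# A lariat-derived cDNA read traverses the junction in inverted order: the
# branchpoint-proximal sequence comes first, then the 5' splice-site
# sequence. Mapping therefore proceeds in two steps: (1) find the junction
# head (first 20 nt, the 5'ss region) as an exact substring of the read;
# (2) align the part of the read *before* the head (the trimmed prefix)
# end-to-end within the junction tail (last 250 nt, the 3'ss region). The
# last aligned base of the prefix is the inferred branchpoint; reverse
# transcriptase frequently misincorporates across the 2'-5' linkage there,
# so an alignment may carry exactly one mismatch at its final base and no
# other mismatch.

#' Map junction heads into reads
#'
#' Finds exact occurrences of each distinct junction head within each read
#' (transcription orientation). Reads matching more than one distinct head
#' sequence, or a head shared by junctions of more than one gene, are
#' discarded as ambiguous.
#'
#' @param junctions junction table from [build_junctions()].
#' @param reads data.frame with `read_id`, `seq`.
#' @return data.frame with `read_id`, `seq`, `head_seq`, `offset` (1-based
#'   start of the head match within the read; one row per occurrence).
#' @export
map_heads <- function(junctions, reads) {
  heads <- unique(junctions$head_seq)
  head_gene <- tapply(junctions$gene_id, junctions$head_seq,
                      function(g) length(unique(g)))
  hits <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    det <- which(stringi::stri_detect_fixed(reads$seq, heads[i]))
    if (!length(det)) next
    loc <- stringi::stri_locate_all_fixed(reads$seq[det], heads[i])
    hits[[i]] <- data.frame(
      read_row = rep(det, vapply(loc, nrow, integer(1))),
      head_seq = heads[i],
      offset = unlist(lapply(loc, function(m) m[, 1]), use.names = FALSE))
  }
  h <- do.call(rbind, hits)
  if (is.null(h))
    return(data.frame(read_id = character(), seq = character(),
                      head_seq = character(), offset = integer()))
  n_heads <- tapply(h$head_seq, h$read_row, function(x) length(unique(x)))
  ambiguous <- as.integer(names(n_heads))[n_heads > 1L]
  h <- h[!(h$read_row %in% ambiguous) & head_gene[h$head_seq] == 1L, ,
         drop = FALSE]
  out <- data.frame(read_id = reads$read_id[h$read_row],
                    seq = reads$seq[h$read_row],
                    head_seq = h$head_seq, offset = h$offset)
  rownames(out) <- NULL
  out
}

#' Trim a read at its head match
#'
#' Returns the branchpoint-proximal prefix: everything before the first base
#' of the 5' splice-site alignment. Prefixes shorter than `min_len` cannot
#' be tail-mapped and yield `NA`.
#'
#' @param seq read sequence.
#' @param offset 1-based start of the head match.
#' @param min_len minimum mappable prefix (default 20).
#' @return the prefix string, or `NA_character_` if too short.
#' @export
trim_read <- function(seq, offset, min_len = 20L) {
  if (offset - 1L < min_len) return(NA_character_)
  stringi::stri_sub(seq, 1L, offset - 1L)
}

# All admissible end-to-end alignments of `prefix` within `tail`:
# zero mismatches, or exactly one mismatch located at the alignment's final
# base (the branchpoint). Returns end offsets (1-based within the tail) and
# mismatch counts. `min_start_local`/`tail_start_local` restrict the
# alignment to begin at or after the junction's 5' splice site (the prefix
# must lie inside the lariat loop).
tail_alignments <- function(prefix, tail, tail_start_local, five_local) {
  Lp <- nchar(prefix)
  ends <- integer(); mm <- integer()
  loc <- stringi::stri_locate_all_fixed(tail, prefix)[[1]]
  if (!is.na(loc[1, 1])) {
    ends <- loc[, 2]
    mm <- rep(0L, length(ends))
  }
  core <- stringi::stri_sub(prefix, 1L, Lp - 1L)
  last <- stringi::stri_sub(prefix, Lp, Lp)
  loc2 <- stringi::stri_locate_all_fixed(tail, core)[[1]]
  if (!is.na(loc2[1, 1])) {
    e2 <- loc2[, 2] + 1L
    ok <- e2 <= nchar(tail) &
      stringi::stri_sub(tail, e2, e2) != last
    if (any(ok)) {
      ends <- c(ends, e2[ok])
      mm <- c(mm, rep(1L, sum(ok)))
    }
  }
  if (length(ends)) {
    start_local <- tail_start_local + (ends - Lp + 1L) - 1L
    keep <- start_local >= five_local
    ends <- ends[keep]; mm <- mm[keep]
  }
  data.frame(end = ends, mismatches = mm)
}

#' Map trimmed prefixes into junction tails and infer branchpoints
#'
#' For each head hit, aligns the read prefix end-to-end within the tails of
#' every junction sharing that head (no indels; zero mismatches or exactly
#' one at the final base). Only best-scoring alignments are kept (fewer
#' mismatches win); within one junction, ties are broken toward the most
#' 3'-ward end (branchpoint closest to the 3' splice site); ties across
#' junctions are retained and later resolved by fractional weights. The
#' branchpoint is the reference base under the alignment's final position.
#'
#' @param hits head-hit table from [map_heads()].
#' @param junctions junction table.
#' @param min_prefix minimum prefix length (default 20).
#' @return unweighted lariat table; one row per retained (read, junction)
#'   alignment, with `bp_pos` (genomic), `bp_local_tail_end`, `bp_mismatch`,
#'   `bp_to_3ss`, `prefix_len`.
#' @export
map_tails <- function(hits, junctions, min_prefix = 20L) {
  jsp <- split(seq_len(nrow(junctions)), junctions$head_seq)
  out <- list(); oi <- 0L
  for (i in seq_len(nrow(hits))) {
    prefix <- trim_read(hits$seq[i], hits$offset[i], min_prefix)
    if (is.na(prefix)) next
    jrows <- jsp[[hits$head_seq[i]]]
    if (is.null(jrows)) next
    cand <- list(); ci <- 0L
    for (jr in jrows) {
      j <- junctions[jr, ]
      tail_start_local <- j$three_local - j$tail_len + 1L
      al <- tail_alignments(prefix, j$tail_seq, tail_start_local,
                            j$five_local)
      if (!nrow(al)) next
      # within-junction: best score, then most 3'-ward end
      al <- al[al$mismatches == min(al$mismatches), , drop = FALSE]
      al <- al[which.max(al$end), , drop = FALSE]
      ci <- ci + 1L
      cand[[ci]] <- cbind(jrow = jr, al)
    }
    if (!ci) next
    cand <- do.call(rbind, cand)
    cand <- cand[cand$mismatches == min(cand$mismatches), , drop = FALSE]
    j <- junctions[cand$jrow, ]
    shift <- j$tail_len - cand$end        # bases between bp and the 3'ss
    oi <- oi + 1L
    out[[oi]] <- data.frame(
      read_id = hits$read_id[i], junction_id = j$junction_id,
      gene_id = j$gene_id, intron_id = j$intron_id, contig = j$contig,
      strand = j$strand, jclass = j$jclass,
      five_class = j$five_class, five_pos = j$five_pos,
      three_class = j$three_class, three_pos = j$three_pos,
      bp_pos = ifelse(j$strand == "+", j$three_pos - shift,
                      j$three_pos + shift),
      bp_mismatch = cand$mismatches == 1L,
      bp_to_3ss = shift,
      prefix_len = nchar(prefix),
      exon_start = if (is.null(j$exon_start)) NA_integer_ else j$exon_start,
      exon_end = if (is.null(j$exon_end)) NA_integer_ else j$exon_end)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read_id = character(), junction_id = character(),
                      gene_id = character(), intron_id = character(),
                      contig = character(), strand = character(),
                      jclass = character(), five_class = character(),
                      five_pos = integer(), three_class = character(),
                      three_pos = integer(), bp_pos = integer(),
                      bp_mismatch = logical(), bp_to_3ss = integer(),
                      prefix_len = integer(), exon_start = integer(),
                      exon_end = integer())
  rownames(res) <- NULL
  res
}

#' Assign fractional weights over ambiguous 3' splice-site resolutions
#'
#' A single (read, 5' splice site, branchpoint) observation may be
#' compatible with several nearby 3'-acting sites whose junction tails all
#' contain the aligned prefix. Each of the k resolutions receives weight
#' 1/k, so every observation contributes exactly one unit of evidence.
#'
#' @param lariats unweighted lariat table from [map_tails()].
#' @return the table with `weight` and `n_alt` columns appended.
#' @export
assign_weights <- function(lariats) {
  if (!nrow(lariats)) {
    lariats$weight <- numeric(); lariats$n_alt <- integer()
    return(lariats)
  }
  key <- paste(lariats$read_id, lariats$five_pos, lariats$bp_pos, sep = "\r")
  k <- as.integer(table(key)[key])
  lariats$weight <- 1 / k
  lariats$n_alt <- k
  lariats
}

#' Full split-read lariat mapping
#'
#' Chains [map_heads()], [map_tails()] and [assign_weights()].
#'
#' @param junctions junction table.
#' @param reads prefiltered reads (`read_id`, `seq`).
#' @param min_prefix minimum branchpoint-proximal prefix length.
#' @return weighted lariat table.
#' @export
map_lariats <- function(junctions, reads, min_prefix = 20L) {
  hits <- map_heads(junctions, reads)
  assign_weights(map_tails(hits, junctions, min_prefix = min_prefix))
}
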