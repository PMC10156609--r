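# Junction library construction: every junction pairs a 5'-acting element
# with a downstream 3'-acting element inside one intron (or intron + exon in
# the distal mode). Reads are mapped to the first `head_len` nt (the 5'
# splice-site region) and the last `tail_len` nt (the 3' splice-site region)
# of each junction.

# Assemble junction rows for one contiguous region. `five_local` /
# `three_local` are 1-based positions of the junction's first and last base
# within `seq` (transcription order).
make_junctions <- function(seq, region, gene_id, intron_id, contig, strand,
                           five_local, three_local, five_class, three_class,
                           jclass, head_len = 20L, tail_len = 250L) {
  len <- three_local - five_local + 1L
  keep <- len >= head_len & five_local < three_local
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    df <- data.frame(gene_id = character(), intron_id = character(),
                     contig = character(), strand = character(),
                     five_class = character(), five_local = integer(),
                     three_class = character(), three_local = integer(),
                     junction_len = integer(), five_pos = integer(),
                     three_pos = integer(), head_seq = character(),
                     tail_len = integer(), tail_seq = character(),
                     jclass = character(), junction_id = character())
    attr(df, "n_dropped_short") <- n_dropped
    return(df)
  }
  df <- data.frame(gene_id = gene_id, intron_id = intron_id,
                   contig = contig, strand = strand,
                   five_class = five_class[keep], five_local = five_local[keep],
                   three_class = three_class[keep],
                   three_local = three_local[keep],
                   junction_len = len[keep])
  if (nrow(df)) {
    df$five_pos <- local_to_genomic(df$five_local, region)
    df$three_pos <- local_to_genomic(df$three_local, region)
    df$head_seq <- stringi::stri_sub(seq, df$five_local,
                                     df$five_local + head_len - 1L)
    df$tail_len <- pmin(tail_len, df$junction_len)
    df$tail_seq <- stringi::stri_sub(seq, df$three_local - df$tail_len + 1L,
                                     df$three_local)
    df$jclass <- jclass[keep]
    df$junction_id <- sprintf("%s|%s:%d|%s:%d", df$gene_id, df$five_class,
                              df$five_pos, df$three_class, df$three_pos)
  }
  attr(df, "n_dropped_short") <- n_dropped
  df
}

#' Build the junction library for a set of introns
#'
#' For each intron, emits the conventional junction (annotated 5'ss to
#' annotated 3'ss) and, separately for the putative and decoy site sets, all
#' ordered pairings: annotated 5'ss to site-as-3'ss, site-as-5'ss to
#' annotated 3'ss, and (optionally) upstream site-as-5'ss to downstream
#' site-as-3'ss. A site acting as a 5'ss contributes sequence starting at
#' its GT; acting as a 3'ss it contributes sequence ending at the G of its
#' YAG (one base before the site position). Junctions shorter than
#' `head_len` are dropped and counted in the `n_dropped_short` attribute.
#'
#' @param genome genome object.
#' @param introns intron table with `intron_id`.
#' @param sites site table from [discover_sites()].
#' @param head_len junction head length in nt (default 20).
#' @param tail_len junction tail length in nt (default 250).
#' @param include_site_pairs also emit site-to-site junctions within an
#'   intron (default `TRUE`).
#' @return data.frame of junctions with head/tail sequences; see
#'   [make_junctions()] columns. `jclass` is `"conventional"`,
#'   `"putative"` or `"decoy"`.
#' @export
build_junctions <- function(genome, introns, sites, head_len = 20L,
                            tail_len = 250L, include_site_pairs = TRUE) {
  out <- vector("list", nrow(introns))
  dropped <- 0L
  site_sp <- split(sites, sites$intron_id)
  for (i in seq_len(nrow(introns))) {
    intr <- introns[i, ]
    L <- intr$length
    seq <- fetch_seq(genome, intr$contig, intr$start, intr$end, intr$strand)
    f5 <- 1L; t3 <- L; c5 <- "annotated"; c3 <- "annotated"
    jc <- "conventional"
    st <- site_sp[[intr$intron_id]]
    if (!is.null(st) && nrow(st)) {
      for (k in c("putative", "decoy")) {
        p <- sort(st$local_pos[st$kind == k])
        if (!length(p)) next
        cls <- if (k == "putative") "RS" else "decoy"
        # annotated 5'ss -> site as 3'ss (junction ends at the G of YAG)
        f5 <- c(f5, rep(1L, length(p)))
        t3 <- c(t3, p - 1L)
        c5 <- c(c5, rep("annotated", length(p)))
        c3 <- c(c3, rep(cls, length(p)))
        jc <- c(jc, rep(k, length(p)))
        # site as 5'ss -> annotated 3'ss (junction starts at the site's GT)
        f5 <- c(f5, p); t3 <- c(t3, rep(L, length(p)))
        c5 <- c(c5, rep(cls, length(p)))
        c3 <- c(c3, rep("annotated", length(p)))
        jc <- c(jc, rep(k, length(p)))
        if (include_site_pairs && length(p) > 1L) {
          pr <- t(combn(p, 2L))             # upstream as 5', downstream as 3'
          f5 <- c(f5, pr[, 1]); t3 <- c(t3, pr[, 2] - 1L)
          c5 <- c(c5, rep(cls, nrow(pr))); c3 <- c(c3, rep(cls, nrow(pr)))
          jc <- c(jc, rep(k, nrow(pr)))
        }
      }
    }
    j <- make_junctions(seq, intr, intr$gene_id, intr$intron_id, intr$contig,
                        intr$strand, f5, t3, c5, c3, jc,
                        head_len = head_len, tail_len = tail_len)
    dropped <- dropped + attr(j, "n_dropped_short")
    out[[i]] <- j
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped_short") <- dropped
  res
}

#' Build distal-exonic junction candidates for a cassette exon
#'
#' Pairs the upstream intron's annotated 5' splice site with every candidate
#' 3' splice-site position inside the exon, with no motif requirement. The
#' junction for a candidate at exonic position `e` spans the whole upstream
#' intron plus the exon up to `e`; a branchpoint inferred for it must later
#' fall strictly inside the exon body (see [filter_exonic_bp()]).
#'
#' @param genome genome object.
#' @param exon one-row data.frame for an internal cassette exon (`contig`,
#'   `start`, `end`, `strand`, `gene_id`).
#' @param upstream_intron one-row intron data.frame immediately upstream of
#'   the exon in transcription order.
#' @param head_len,tail_len as in [build_junctions()].
#' @return junction data.frame with `jclass = "distal"`, `three_class =
#'   "exonic"`, plus `exon_start`/`exon_end` columns for the exon-body
#'   filter.
#' @export
build_distal_junctions <- function(genome, exon, upstream_intron,
                                   head_len = 20L, tail_len = 250L) {
  intr <- upstream_intron
  stopifnot(intr$strand == exon$strand, intr$contig == exon$contig)
  adjacent <- if (intr$strand == "+") intr$end + 1L == exon$start
              else exon$end + 1L == intr$start
  if (!adjacent) stop("intron is not immediately upstream of the exon")
  region <- list(start = min(intr$start, exon$start),
                 end = max(intr$end, exon$end), strand = intr$strand)
  seq <- fetch_seq(genome, intr$contig, region$start, region$end, intr$strand)
  L <- intr$length
  exon_len <- exon$end - exon$start + 1L
  e <- seq_len(exon_len)                     # candidate 3'ss = exonic base e
  j <- make_junctions(seq, region, exon$gene_id, intr$intron_id, intr$contig,
                      intr$strand, rep(1L, exon_len), L + e,
                      rep("annotated", exon_len), rep("exonic", exon_len),
                      rep("distal", exon_len),
                      head_len = head_len, tail_len = tail_len)
  j$exon_start <- exon$start
  j$exon_end <- exon$end
  rownames(j) <- NULL
  j
}

#' Write a junction library as FASTA
#'
#' Emits one record per junction with the structured header
#' `gene|5class:coord|3class:coord` and the head and tail sequences joined
#' (head first; for junctions no longer than the tail window the full
#' junction sequence equals the tail).
#'
#' @param junctions junction table.
#' @param path output path.
#' @param what `"tail"` (default), `"head"`, or `"both"` concatenated.
#' @return `path`, invisibly.
#' @export
write_junctions_fasta <- function(junctions, path, what = c("tail", "head",
                                                            "both")) {
  what <- match.arg(what)
  s <- switch(what, head = junctions$head_seq, tail = junctions$tail_seq,
              both = paste0(junctions$head_seq, junctions$tail_seq))
  ss <- Biostrings::DNAStringSet(setNames(s, junctions$junction_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
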