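# The filter cascade: consecutive filtering of mapped junctions, with
# per-stage survivor accounting for putative and decoy classes and a
# decoy-based empirical FDR at every stage.

#' Summarise read support per junction
#'
#' @param lariats weighted lariat table.
#' @return data.frame, one row per junction, with read counts, total weight,
#'   weighted branchpoint-mismatch support and the junction class.
#' @export
junction_support <- function(lariats) {
  if (!nrow(lariats)) {
    return(data.frame(junction_id = character(), jclass = character(),
                      n_reads = integer(), n_total_weight = numeric(),
                      n_bp_mismatch_weight = numeric(),
                      has_bp_mismatch = logical()))
  }
  sp <- split(seq_len(nrow(lariats)), lariats$junction_id)
  out <- data.frame(
    junction_id = names(sp),
    jclass = vapply(sp, function(i) lariats$jclass[i[1]], character(1)),
    n_reads = vapply(sp, length, integer(1)),
    n_total_weight = vapply(sp, function(i) sum(lariats$weight[i]),
                            numeric(1)),
    n_bp_mismatch_weight = vapply(sp, function(i)
      sum(lariats$weight[i][lariats$bp_mismatch[i]]), numeric(1)),
    has_bp_mismatch = vapply(sp, function(i) any(lariats$bp_mismatch[i]),
                             logical(1)))
  rownames(out) <- NULL
  out
}

#' Existence filter: at least one branchpoint-mismatch read
#'
#' Junction-level predicate: the junction must be supported by one or more
#' reads (regardless of weight) carrying the reverse-transcriptase mismatch
#' at the branchpoint.
#'
#' @param support output of [junction_support()].
#' @return logical keep vector over junctions.
#' @export
require_bp_mismatch <- function(support) {
  support$has_bp_mismatch
}

#' High-confidence filter
#'
#' Junction-level predicate combining (a) a weighted branchpoint-mismatch
#' read fraction of at least `mismatch_fraction`, and (b) genomic
#' uniqueness of the mapped regions: the 20-mer starting at the 5' splice
#' site and the 20-mer ending at each supporting branchpoint must each
#' occur exactly once in the genome (both strands searched), guarding
#' against gene duplications masquerading as recursive sites.
#'
#' @param support output of [junction_support()].
#' @param lariats the lariat table the support was built from.
#' @param genome genome object.
#' @param mismatch_fraction minimum weighted mismatch fraction
#'   (default 0.05).
#' @param flank mapped-region length (default 20).
#' @return logical keep vector over `support` rows.
#' @export
high_confidence <- function(support, lariats, genome,
                            mismatch_fraction = 0.05, flank = 20L) {
  if (!nrow(support)) return(logical())
  frac_ok <- support$n_bp_mismatch_weight >=
    mismatch_fraction * support$n_total_weight
  uniq_ok <- vapply(seq_len(nrow(support)), function(i) {
    rows <- lariats[lariats$junction_id == support$junction_id[i], ,
                    drop = FALSE]
    pos <- rows$strand == "+"
    k5 <- fetch_seq(genome, rows$contig[1],
                    if (pos[1]) rows$five_pos[1] else
                      rows$five_pos[1] - flank + 1L,
                    if (pos[1]) rows$five_pos[1] + flank - 1L else
                      rows$five_pos[1],
                    rows$strand[1])
    ub <- !duplicated(rows$bp_pos)
    kb <- fetch_seq(genome, rows$contig[ub],
                    ifelse(pos[ub], rows$bp_pos[ub] - flank + 1L,
                           rows$bp_pos[ub]),
                    ifelse(pos[ub], rows$bp_pos[ub],
                           rows$bp_pos[ub] + flank - 1L),
                    rows$strand[ub])
    all(genome_kmer_count(genome, c(k5, kb)) == 1)
  }, logical(1))
  frac_ok & uniq_ok
}

#' Run the filter cascade
#'
#' Applies the consecutive filtering steps to a mapped lariat table,
#' recording survivors (putative and decoy junctions separately) and the
#' decoy-based empirical FDR after every stage. Intronic order:
#' branchpoint-mismatch existence, high confidence, proximity to annotated
#' splice sites, repeat overlap, branchpoint distance, self-primed. In
#' distal mode the proximity and repeat stages are replaced by the
#' exon-body branchpoint filter. Every stage can be toggled off via
#' `stages`; filters only remove, so survivor counts are monotonically
#' non-increasing and the final set does not depend on stage order.
#'
#' @param lariats weighted lariat table from [map_lariats()].
#' @param genome genome object.
#' @param sites site table from [discover_sites()] (used for the per-site
#'   decoy normalisation of the FDR); may be `NULL` in distal mode.
#' @param annotated_ss table from [annotated_splice_sites()] (intronic
#'   mode).
#' @param repeats optional repeat interval table (see [filter_repeats()]).
#' @param mode `"intronic"` or `"distal"`.
#' @param stages character vector of stages to run (default: all for the
#'   mode).
#' @param proximity_window,bp_dist_min,bp_dist_max,mismatch_fraction,selfprime_k
#'   filter parameters; defaults are the method's standard values.
#' @return object of class `rs_filter_report`: a list with `report` (the
#'   per-stage accounting), `lariats` (surviving reads), `junctions`
#'   (surviving junction support) and `sites` (final recursive-site table).
#' @export
run_cascade <- function(lariats, genome, sites = NULL, annotated_ss = NULL,
                        repeats = NULL, mode = c("intronic", "distal"),
                        stages = NULL, proximity_window = 100L,
                        bp_dist_min = 10L, bp_dist_max = 60L,
                        mismatch_fraction = 0.05, selfprime_k = 5L) {
  mode <- match.arg(mode)
  all_stages <- if (mode == "intronic") {
    c("bp_mismatch", "high_confidence", "proximity", "repeats",
      "bp_distance", "self_primed")
  } else {
    c("bp_mismatch", "high_confidence", "exonic_bp", "bp_distance",
      "self_primed")
  }
  stages <- stages %||% all_stages
  stopifnot(all(stages %in% all_stages))
  cur <- if (mode == "intronic") {
    lariats[lariats$jclass %in% c("putative", "decoy"), , drop = FALSE]
  } else {
    lariats[lariats$jclass == "distal", , drop = FALSE]
  }
  n_put_sites <- if (!is.null(sites)) sum(sites$kind == "putative") else NA
  n_dec_sites <- if (!is.null(sites)) sum(sites$kind == "decoy") else NA

  acct <- function(stage, lar) {
    sup <- junction_support(lar)
    pw <- sum(lar$weight[lar$jclass != "decoy"])
    dw <- sum(lar$weight[lar$jclass == "decoy"])
    fdr <- if (!is.null(sites) && n_dec_sites > 0) {
      empirical_fdr(pw, dw, n_put_sites, n_dec_sites)$fdr
    } else NA_real_
    data.frame(stage = stage,
               putative_junctions = sum(sup$jclass != "decoy"),
               decoy_junctions = sum(sup$jclass == "decoy"),
               putative_weight = pw, decoy_weight = dw, fdr = fdr)
  }
  report <- acct("mapped", cur)

  keep_junctions <- function(lar, keep, support) {
    lar[lar$junction_id %in% support$junction_id[keep], , drop = FALSE]
  }
  for (st in all_stages[all_stages %in% stages]) {
    cur <- switch(st,
      bp_mismatch = {
        sup <- junction_support(cur)
        keep_junctions(cur, require_bp_mismatch(sup), sup)
      },
      high_confidence = {
        sup <- junction_support(cur)
        keep_junctions(cur, high_confidence(sup, cur, genome,
                                            mismatch_fraction), sup)
      },
      proximity = cur[filter_proximity(cur, annotated_ss,
                                       proximity_window), , drop = FALSE],
      repeats = cur[filter_repeats(cur, repeats), , drop = FALSE],
      bp_distance = cur[filter_bp_distance(cur$bp_to_3ss, bp_dist_min,
                                           bp_dist_max), , drop = FALSE],
      exonic_bp = cur[filter_exonic_bp(cur), , drop = FALSE],
      self_primed = cur[filter_self_primed(cur, genome, selfprime_k), ,
                        drop = FALSE])
    report <- rbind(report, acct(st, cur))
  }
  rownames(report) <- NULL
  structure(list(report = report, lariats = cur,
                 junctions = junction_support(cur),
                 sites = surviving_sites(cur)),
            class = "rs_filter_report")
}

# Distinct recursive-site coordinates supported by surviving junctions. The
# site coordinate is the first base of its reconstituted 5'ss GT, so a site
# acting as a 3'ss (junction ending at the G of its YAG) sits one base
# downstream of the junction end in transcription order.
surviving_sites <- function(lariats) {
  if (!nrow(lariats)) {
    return(data.frame(contig = character(), strand = character(),
                      pos = integer(), role = character(),
                      gene_id = character(), intron_id = character(),
                      kind = character(), n_reads = integer(),
                      weight = numeric()))
  }
  recs <- list()
  f5 <- lariats$five_class %in% c("RS", "decoy", "exonic")
  if (any(f5)) {
    recs[[1]] <- data.frame(contig = lariats$contig[f5],
                            strand = lariats$strand[f5],
                            pos = lariats$five_pos[f5], role = "5ss",
                            gene_id = lariats$gene_id[f5],
                            intron_id = lariats$intron_id[f5],
                            kind = lariats$five_class[f5],
                            weight = lariats$weight[f5])
  }
  t3 <- lariats$three_class %in% c("RS", "decoy", "exonic")
  if (any(t3)) {
    pos <- ifelse(lariats$strand[t3] == "+", lariats$three_pos[t3] + 1L,
                  lariats$three_pos[t3] - 1L)
    recs[[2]] <- data.frame(contig = lariats$contig[t3],
                            strand = lariats$strand[t3],
                            pos = pos, role = "3ss",
                            gene_id = lariats$gene_id[t3],
                            intron_id = lariats$intron_id[t3],
                            kind = lariats$three_class[t3],
                            weight = lariats$weight[t3])
  }
  x <- do.call(rbind, recs)
  key <- paste(x$contig, x$strand, x$pos, x$role, sep = ":")
  agg <- data.frame(x[!duplicated(key), c("contig", "strand", "pos", "role",
                                          "gene_id", "intron_id", "kind")],
                    n_reads = as.integer(table(key)[key[!duplicated(key)]]),
                    weight = as.numeric(tapply(x$weight, key,
                                               sum)[key[!duplicated(key)]]))
  agg <- agg[order(agg$contig, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.rs_filter_report <- function(x, ...) {
  cat("Recursive-splicing filter cascade\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("\nFinal: %d junction(s), %d site record(s), %d read(s)\n",
              nrow(x$junctions), nrow(x$sites), nrow(x$lariats)))
  invisible(x)
}
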