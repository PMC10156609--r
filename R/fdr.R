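#' Decoy-based empirical false discovery rate
#'
#' Decoy sites are random intronic positions stripped of splice-like
#' context, so any read weight they accumulate estimates the background
#' rate of spurious lariat calls. The expected number of false putative
#' hits is the per-decoy-site hit rate scaled to the number of putative
#' sites (the per-site normalisation corrects for decoy filtering leaving
#' fewer than the nominal five decoys per putative site); the FDR is that
#' expectation over the observed putative hits, clipped to [0, 1].
#'
#' @param putative_hits weighted hit count on putative junctions.
#' @param decoy_hits weighted hit count on decoy junctions.
#' @param n_putative_sites,n_decoy_sites number of candidate sites of each
#'   class generated at discovery time.
#' @param stage optional stage label.
#' @return data.frame with the inputs and `fdr` (`NA` when
#'   `putative_hits` is zero).
#' @export
empirical_fdr <- function(putative_hits, decoy_hits, n_putative_sites,
                          n_decoy_sites, stage = NA_character_) {
  stopifnot(putative_hits >= 0, decoy_hits >= 0, n_decoy_sites > 0)
  fdr <- if (putative_hits == 0) NA_real_ else {
    min(1, max(0, (decoy_hits / n_decoy_sites * n_putative_sites) /
                  putative_hits))
  }
  data.frame(stage = stage, putative_hits = putative_hits,
             decoy_hits = decoy_hits, n_putative_sites = n_putative_sites,
             n_decoy_sites = n_decoy_sites, fdr = fdr)
}
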