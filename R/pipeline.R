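#' Pipeline configuration
#'
#' Collects the numeric knobs of the whole pipeline with the method's
#' standard defaults: 20-nt junction heads, 250-nt tails, five decoys per
#' putative site, a 100-nt proximity window, a 10-60-nt branchpoint
#' distance window, a 5\% branchpoint-mismatch read fraction, 5-nt
#' self-primed comparison, 1000 Monte-Carlo samples, a 25-nt branchpoint
#' offset and a \{75, 100, 150\}-nt read-length grid.
#'
#' @param head_len,tail_len junction head/tail lengths (nt).
#' @param decoys_per_site decoys drawn per putative site.
#' @param decoy_window decoy exclusion distance (nt).
#' @param proximity_window annotated-splice-site proximity window (nt).
#' @param bp_dist_min,bp_dist_max branchpoint-to-3'ss distance range (nt).
#' @param mismatch_fraction minimum weighted branchpoint-mismatch read
#'   fraction.
#' @param selfprime_k self-primed comparison length (nt).
#' @param ambiguous_max_frac maximum ambiguous-base fraction per read.
#' @param mismatch_rate linear-alignment mismatch budget per base.
#' @param min_prefix minimum branchpoint-proximal prefix (nt).
#' @param mc_samples Monte-Carlo positions per intron.
#' @param bp_offset assumed branchpoint offset upstream of the 3'ss (nt).
#' @param read_len_grid read lengths for the informative-read model.
#' @param mode `"intronic"` or `"distal"`.
#' @param seed master seed for the decoy draw.
#' @return an `rs_config` list.
#' @export
rs_config <- function(head_len = 20L, tail_len = 250L, decoys_per_site = 5L,
                      decoy_window = 250L, proximity_window = 100L,
                      bp_dist_min = 10L, bp_dist_max = 60L,
                      mismatch_fraction = 0.05, selfprime_k = 5L,
                      ambiguous_max_frac = 0.05, mismatch_rate = 0.0133,
                      min_prefix = 20L, mc_samples = 1000L, bp_offset = 25L,
                      read_len_grid = c(75L, 100L, 150L),
                      mode = "intronic", seed = 1L) {
  structure(as.list(environment()), class = "rs_config")
}

#' Run the full recursive-splicing discovery pipeline
#'
#' Chains every stage on in-memory objects: constitutive-intron extraction,
#' motif scan and decoy generation, junction construction, read
#' prefiltering (ambiguity and linear subtraction), split-read lariat
#' mapping with branchpoint inference and fractional weights, and the
#' filter cascade with decoy-based empirical FDR.
#'
#' @param genome genome object ([load_genome()]).
#' @param exons exon table ([load_annotation()]).
#' @param reads read table ([load_reads_fastq()]).
#' @param repeats optional repeat intervals (see [filter_repeats()]).
#' @param config an [rs_config()].
#' @return list with `sites`, `junctions`, `prefilter_counts`, `lariats`,
#'   `cascade` (an `rs_filter_report`) and the echoed `config`.
#' @export
run_pipeline <- function(genome, exons, reads, repeats = NULL,
                         config = rs_config()) {
  introns <- constitutive_introns(exons)
  sites <- discover_sites(genome, introns,
                          n_decoys_per_site = config$decoys_per_site,
                          window = config$decoy_window, seed = config$seed)
  junctions <- build_junctions(genome, introns, sites,
                               head_len = config$head_len,
                               tail_len = config$tail_len)
  r1 <- filter_ambiguous(reads, config$ambiguous_max_frac)
  tx <- transcript_sequences(genome, exons)
  r2 <- subtract_mapped(r1, genome, tx, config$mismatch_rate)
  counts <- data.frame(
    stage = c("input", "ambiguous_removed", "linear_removed", "lariat_search"),
    n = c(nrow(reads), attr(r1, "n_removed"),
          attr(r2, "n_tx_removed") + attr(r2, "n_genome_removed"),
          nrow(r2)))
  lariats <- map_lariats(junctions, r2, min_prefix = config$min_prefix)
  ann_ss <- annotated_splice_sites(derive_introns(exons))
  cascade <- run_cascade(lariats, genome, sites, ann_ss, repeats,
                         mode = "intronic",
                         proximity_window = config$proximity_window,
                         bp_dist_min = config$bp_dist_min,
                         bp_dist_max = config$bp_dist_max,
                         mismatch_fraction = config$mismatch_fraction,
                         selfprime_k = config$selfprime_k)
  list(introns = introns, sites = sites, junctions = junctions,
       prefilter_counts = counts, lariats = lariats, cascade = cascade,
       config = config)
}
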