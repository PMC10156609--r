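# Cascade accounting, junction-level predicates, and the empirical FDR.

test_that("empirical FDR follows the per-site-normalised formula", {
  r <- empirical_fdr(100, 5, 2000, 1000)
  expect_equal(r$fdr, 0.10)
  expect_equal(empirical_fdr(100, 0, 2000, 1000)$fdr, 0)
  expect_equal(empirical_fdr(1, 1e6, 2000, 1000)$fdr, 1)   # clipped
  expect_true(is.na(empirical_fdr(0, 5, 2000, 1000)$fdr))
  # scale invariance in the counts
  for (c in c(0.5, 3, 17)) {
    expect_equal(empirical_fdr(100 * c, 5 * c, 2000 * c, 1000 * c)$fdr,
                 0.10)
  }
  expect_error(empirical_fdr(1, 1, 10, 0))
})

test_that("mismatch-existence is unweighted, the 5% fraction is weighted", {
  lar <- data.frame(
    read_id = sprintf("r%02d", 1:20),
    junction_id = "j1", jclass = "putative",
    weight = rep(1, 20),
    bp_mismatch = c(TRUE, rep(FALSE, 19)))
  sup <- junction_support(lar)
  expect_true(require_bp_mismatch(sup))
  # 1/20 = 5% meets the >= 5% criterion
  expect_equal(sup$n_bp_mismatch_weight / sup$n_total_weight, 0.05)
  lar0 <- transform(lar, bp_mismatch = FALSE)
  expect_false(require_bp_mismatch(junction_support(lar0)))
  # a fractional-weight mismatch read still satisfies existence
  larw <- lar[1, ]; larw$weight <- 0.5
  expect_true(require_bp_mismatch(junction_support(larw)))
})

test_that("high-confidence combines the fraction and genomic uniqueness", {
  fx <- junction_fixture(put_local = 1000L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  conv <- j[j$jclass == "conventional", ]
  mk_lar <- function(n, n_mm, bp_off = 25L) {
    data.frame(read_id = sprintf("r%03d", seq_len(n)),
               junction_id = conv$junction_id, jclass = "putative",
               gene_id = "g", contig = "chr", strand = "+",
               five_pos = conv$five_pos, three_pos = conv$three_pos,
               bp_pos = conv$three_pos - bp_off,
               bp_mismatch = seq_len(n) <= n_mm, weight = 1)
  }
  lar <- mk_lar(20L, 1L)
  expect_true(high_confidence(junction_support(lar), lar, fx$genome))
  lar0 <- mk_lar(21L, 1L)   # 1/21 < 5%
  expect_false(high_confidence(junction_support(lar0), lar0, fx$genome))
  # duplicating the 5'ss 20-mer elsewhere breaks uniqueness
  g2 <- unclass(fx$genome)
  g2["extra"] <- paste0(strrep("A", 30), conv$head_seq, strrep("A", 30))
  g2 <- as_genome(g2)
  expect_false(high_confidence(junction_support(lar), lar, g2))
})

test_that("cascade survivors shrink monotonically on the study simulation", {
  run <- study_run()
  rep <- run$res$cascade$report
  expect_true(all(diff(rep$putative_junctions) <= 0))
  expect_true(all(diff(rep$decoy_junctions) <= 0))
  expect_true(all(diff(rep$putative_weight) <= 0))
  expect_true(all(diff(rep$decoy_weight) <= 0))
})

test_that("disabling a filter can only enlarge the surviving set", {
  run <- study_run()
  sim <- run$sim; res <- run$res
  full <- res$cascade$junctions$junction_id
  for (drop_stage in c("proximity", "bp_distance", "self_primed")) {
    stages <- setdiff(c("bp_mismatch", "high_confidence", "proximity",
                        "repeats", "bp_distance", "self_primed"),
                      drop_stage)
    part <- suppressWarnings(run_cascade(
      res$lariats, sim$genome, res$sites,
      annotated_splice_sites(derive_introns(sim$exons)), sim$repeats,
      stages = stages))
    expect_true(all(full %in% part$junctions$junction_id))
  }
})

test_that("stage order changes accounting but not the final set", {
  run <- study_run()
  sim <- run$sim; res <- run$res
  ann <- annotated_splice_sites(derive_introns(sim$exons))
  full <- sort(res$cascade$junctions$junction_id)
  # run the same pure predicates in a different order by chaining two
  # cascades: late filters first, then the early ones
  first <- suppressWarnings(run_cascade(
    res$lariats, sim$genome, res$sites, ann, sim$repeats,
    stages = c("bp_distance", "self_primed")))
  second <- suppressWarnings(run_cascade(
    first$lariats, sim$genome, res$sites, ann, sim$repeats,
    stages = c("bp_mismatch", "high_confidence", "proximity", "repeats")))
  expect_identical(sort(second$junctions$junction_id), full)
})

test_that("a decoy-only input reports zero putative hits and NA FDR", {
  run <- study_run()
  res <- run$res
  dec <- res$lariats[res$lariats$jclass == "decoy", ]
  out <- suppressWarnings(run_cascade(
    dec, run$sim$genome, res$sites,
    annotated_splice_sites(derive_introns(run$sim$exons)),
    run$sim$repeats))
  expect_equal(out$report$putative_junctions[1], 0L)
  expect_true(all(is.na(out$report$fdr)))
})

test_that("distal mode keeps only exon-body branchpoints in window", {
  fx <- cassette_fixture()
  introns <- derive_introns(fx$exons)
  up <- introns[introns$transcript_id == "t1" & introns$start == 201L, ]
  up$intron_id <- "up1"
  exon <- data.frame(contig = "chrT", start = 301L, end = 420L,
                     strand = "+", gene_id = "gT")
  dj <- build_distal_junctions(fx$genome, exon, up)
  # construct reads for a distal lariat: branchpoint inside the exon,
  # 25 nt upstream of a candidate 3'ss at exon base 80 (genomic 380)
  three <- 380L; bp <- three - 25L
  region_seq <- fetch_seq(fx$genome, "chrT", 201L, 420L, "+")
  prefix <- substr(region_seq, bp - 200L - 29L, bp - 200L)
  reads <- data.frame(
    read_id = c("mm", "clean"),
    seq = paste0(prefix, substr(region_seq, 1, 45)))
  substr(reads$seq[1], 30, 30) <-
    setdiff(c("A", "C", "G", "T"), substr(reads$seq[1], 30, 30))[1]
  lar <- map_lariats(dj, reads)
  got <- lar[lar$three_pos == three, ]
  expect_true(all(got$bp_pos == bp))
  out <- run_cascade(lar, fx$genome, mode = "distal",
                     mismatch_fraction = 0.05)
  expect_true(three %in% out$lariats$three_pos)
  expect_true(all(out$lariats$bp_pos > 301L & out$lariats$bp_pos < 420L))
  expect_true(all(filter_bp_distance(out$lariats$bp_to_3ss)))
})
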