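# Shared fixtures. The study-condition simulation (200 genes, 50 planted
# sites, all artifact classes) plus its full pipeline run are computed once
# per session and reused by the cascade and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

study_run <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- sim_config(seed = 1L)
    sim <- simulate_dataset(cfg)
    res <- suppressWarnings(
      run_pipeline(sim$genome, sim$exons, sim$reads, repeats = sim$repeats,
                   config = rs_config(seed = cfg$seed)))
    .fixture_env$study <- list(cfg = cfg, sim = sim, res = res)
  }
  .fixture_env$study
}

# Smaller error-free simulation for the exact round-trip checks.
errorfree_run <- function() {
  if (is.null(.fixture_env$errorfree)) {
    cfg <- sim_config(n_genes = 50L, n_rs_sites = 15L,
                      n_duplicated_sites = 1L, seq_error_rate = 0,
                      n_background_reads = 400L, seed = 3L)
    sim <- simulate_dataset(cfg)
    lariats <- map_lariats(sim$junctions, sim$reads)
    .fixture_env$errorfree <- list(cfg = cfg, sim = sim, lariats = lariats)
  }
  .fixture_env$errorfree
}

# One intron of `len` nt (flanked by 100 nt on each side) with optional
# planted recursive-site motifs, as a ready-to-use genome + intron + sites
# bundle for junction and mapping tests. Transcription-order sequence `seq`
# is returned so reads can be constructed by direct slicing.
junction_fixture <- function(put_local = integer(), dec_local = integer(),
                             len = 2000L, strand = "+", seed = 21L) {
  set.seed(seed)
  s <- random_dna(len, probs = c(0.35, 0.15, 0.35, 0.15))
  for (p in put_local) substr(s, p - 9, p + 1) <- "TTTTTTCAGGT"
  flank <- random_dna(100L)
  contig <- if (strand == "+") paste0(flank, s, flank) else
    paste0(flank, revcomp(s), flank)
  genome <- as_genome(c(chr = contig))
  intron <- data.frame(contig = "chr", start = 101L, end = 100L + len,
                       strand = strand, gene_id = "g",
                       five_prime_ss = if (strand == "+") 101L else 100L + len,
                       three_prime_ss = if (strand == "+") 100L + len else 101L,
                       length = len, constitutive = TRUE,
                       intron_id = "g:chr:i1")
  sites <- data.frame(
    intron_id = "g:chr:i1", gene_id = "g", contig = "chr", strand = strand,
    kind = rep(c("putative", "decoy"), c(length(put_local),
                                         length(dec_local))),
    local_pos = c(put_local, dec_local))
  sites$pos <- rslariat:::local_to_genomic(sites$local_pos, intron[1, ])
  sites$site_id <- paste0(sites$kind, "@", sites$pos)
  list(genome = genome, intron = intron, sites = sites, seq = s)
}

# Tiny hand-built gene with a cassette exon, for annotation and distal-mode
# tests. Plus strand: exon1 [101,200], exon2 [301,420] (cassette),
# exon3 [521,620]; transcript t1 has all three, t2 skips exon2.
cassette_fixture <- function(seed = 11L) {
  set.seed(seed)
  contig <- random_dna(800L)
  # canonical intron boundaries for both introns of t1
  substr(contig, 201, 202) <- "GT"; substr(contig, 299, 300) <- "AG"
  substr(contig, 421, 422) <- "GT"; substr(contig, 519, 520) <- "AG"
  genome <- as_genome(c(chrT = contig))
  exons <- data.frame(
    contig = "chrT",
    start = c(101L, 301L, 521L, 101L, 521L),
    end   = c(200L, 420L, 620L, 200L, 620L),
    strand = "+", gene_id = "gT",
    transcript_id = c("t1", "t1", "t1", "t2", "t2"))
  exons <- rslariat:::validate_exons(exons)
  list(genome = genome, exons = exons)
}
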