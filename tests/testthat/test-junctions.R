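# Junction library construction: pairing rules, head/tail extraction,
# strand handling, and the distal-exonic variant.

test_that("one site yields conventional plus two mixed junctions", {
  fx <- junction_fixture(put_local = 1000L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  expect_equal(nrow(j), 3L)
  expect_equal(sum(j$jclass == "conventional"), 1L)
  expect_equal(sum(j$jclass == "putative"), 2L)
  expect_equal(sum(j$five_class == "RS" & j$three_class == "RS"), 0L)
})

test_that("two ordered sites yield 1 + 2 + 2 + 1 junctions", {
  fx <- junction_fixture(put_local = c(800L, 1400L))
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  expect_equal(nrow(j), 6L)
  expect_equal(sum(j$jclass == "conventional"), 1L)
  expect_equal(sum(j$five_class == "RS" & j$three_class == "RS"), 1L)
  ss <- j[j$five_class == "RS" & j$three_class == "RS", ]
  expect_equal(ss$five_local, 800L)     # upstream site donates the 5'ss
  expect_equal(ss$three_local, 1399L)   # downstream site ends at its YAG G
  # site pairs can be switched off
  j2 <- build_junctions(fx$genome, fx$intron, fx$sites,
                        include_site_pairs = FALSE)
  expect_equal(nrow(j2), 5L)
})

test_that("head and tail are verbatim slices of the junction sequence", {
  fx <- junction_fixture(put_local = 301L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  # annotated 5'ss -> site as 3'ss: junction of length 300
  ja <- j[j$three_class == "RS", ]
  expect_equal(ja$junction_len, 300L)
  jseq <- substr(fx$seq, ja$five_local, ja$three_local)
  expect_identical(ja$head_seq, substr(jseq, 1, 20))
  expect_identical(ja$tail_seq, substr(jseq, 300 - 250 + 1, 300))
  expect_equal(ja$tail_len, 250L)
  # short junction keeps the whole sequence as tail
  jc <- j[j$five_class == "RS", ]
  expect_equal(jc$tail_len, min(250L, jc$junction_len))
})

test_that("junctions shorter than the head are dropped and counted", {
  fx <- junction_fixture(put_local = 1990L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  # site-as-5'ss junction is only 11 nt long: dropped
  expect_equal(sum(j$five_class == "RS"), 0L)
  expect_equal(sum(j$three_class == "RS"), 1L)
  expect_gte(attr(j, "n_dropped_short"), 1L)
})

test_that("minus-strand junction sequences are reverse-complemented", {
  fxp <- junction_fixture(put_local = 1000L, strand = "+")
  fxm <- junction_fixture(put_local = 1000L, strand = "-")
  jp <- build_junctions(fxp$genome, fxp$intron, fxp$sites)
  jm <- build_junctions(fxm$genome, fxm$intron, fxm$sites)
  # same transcription-order sequences on both strands
  expect_identical(sort(jp$head_seq), sort(jm$head_seq))
  expect_identical(sort(jp$tail_seq), sort(jm$tail_seq))
  # and the genomic coordinates mirror
  cm <- jm[jm$jclass == "conventional", ]
  expect_equal(cm$five_pos, 2100L)
  expect_equal(cm$three_pos, 101L)
  # fetch at the genomic tail coordinates reproduces the stored tail
  expect_identical(fetch_seq(fxm$genome, "chr", cm$three_pos,
                             cm$three_pos + cm$tail_len - 1L, "-"),
                   cm$tail_seq)
})

test_that("distal junctions pair the intron 5'ss with every exonic base", {
  fx <- cassette_fixture()
  introns <- derive_introns(fx$exons)
  up <- introns[introns$transcript_id == "t1" & introns$start == 201L, ]
  up$intron_id <- "up1"
  exon <- data.frame(contig = "chrT", start = 301L, end = 420L,
                     strand = "+", gene_id = "gT")
  dj <- build_distal_junctions(fx$genome, exon, up)
  expect_equal(nrow(dj), 120L)              # one per candidate exonic 3'ss
  expect_true(all(dj$jclass == "distal"))
  expect_true(all(dj$five_pos == 201L))
  expect_equal(sort(dj$three_pos), 301:420)
  # candidate at the exon's final base spans intron plus whole exon
  last <- dj[dj$three_pos == 420L, ]
  expect_equal(last$junction_len, 220L)
  # head comes from the intron 5'ss
  expect_identical(last$head_seq,
                   fetch_seq(fx$genome, "chrT", 201L, 220L, "+"))
})

test_that("minus-strand distal junction tails round-trip through fetch", {
  set.seed(31)
  contig <- random_dna(800L)
  genome <- as_genome(c(chrM = contig))
  # minus strand: exon [101,220] downstream (in transcription order) of the
  # intron [221,320]
  up <- data.frame(contig = "chrM", start = 221L, end = 320L, strand = "-",
                   gene_id = "g", five_prime_ss = 320L,
                   three_prime_ss = 221L, length = 100L,
                   intron_id = "m1")
  exon <- data.frame(contig = "chrM", start = 101L, end = 220L,
                     strand = "-", gene_id = "g")
  dj <- build_distal_junctions(genome, exon, up)
  expect_equal(nrow(dj), 120L)
  k <- dj[60, ]
  expect_identical(k$tail_seq,
                   fetch_seq(genome, "chrM", k$three_pos,
                             k$three_pos + k$tail_len - 1L, "-"))
})
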