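test_that("genome loading validates and fetches strand-correct sequence", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr2 description text", "AACGT"), fa)
  g <- load_genome(fa)
  expect_setequal(names(g), c("chr1", "chr2"))
  expect_identical(fetch_seq(g, "chr1", 1, 4, "+"), "ACGT")
  # ACGT is its own reverse complement
  expect_identical(fetch_seq(g, "chr1", 1, 4, "-"), "ACGT")
  # hand-computed reverse complement of "AC" (positions 2-3 of AACGT)
  expect_identical(fetch_seq(g, "chr2", 2, 3, "+"), "AC")
  expect_identical(fetch_seq(g, "chr2", 2, 3, "-"), "GT")
  expect_error(fetch_seq(g, "chrX", 1, 2), "unknown contig")
  expect_error(fetch_seq(g, "chr1", 0, 2), "bounds")
  expect_error(as_genome(c(chr1 = "ACGU")), "non-ACGTN")
  expect_error(as_genome(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("reverse complement is an involution", {
  set.seed(42)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("introns are the exact gaps between consecutive exons", {
  ex <- data.frame(contig = "c", start = c(1L, 201L), end = c(100L, 300L),
                   strand = "+", gene_id = "g", transcript_id = "t")
  ir <- derive_introns(rslariat:::validate_exons(ex))
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$start, 101L)
  expect_equal(ir$end, 200L)
  expect_equal(ir$five_prime_ss, 101L)
  expect_equal(ir$three_prime_ss, 200L)
  # single-exon transcript has no introns
  ex1 <- data.frame(contig = "c", start = 1L, end = 100L, strand = "+",
                    gene_id = "g", transcript_id = "t")
  expect_equal(nrow(derive_introns(rslariat:::validate_exons(ex1))), 0L)
  # minus strand mirrors the splice-site coordinates
  exm <- ex; exm$strand <- "-"
  irm <- derive_introns(rslariat:::validate_exons(exm))
  expect_equal(irm$five_prime_ss, 200L)
  expect_equal(irm$three_prime_ss, 101L)
  # intron set partitions the transcript span minus exons: no overlap, no gap
  ex3 <- data.frame(contig = "c", start = c(1L, 151L, 401L),
                    end = c(100L, 300L, 500L), strand = "+",
                    gene_id = "g", transcript_id = "t")
  ir3 <- derive_introns(rslariat:::validate_exons(ex3))
  covered <- sort(c(unlist(Map(seq, ex3$start, ex3$end)),
                    unlist(Map(seq, ir3$start, ir3$end))))
  expect_identical(covered, 1:500)
})

test_that("GTF and BED12 annotations round-trip through rtracklayer", {
  ex <- data.frame(contig = "chr1", start = c(11L, 101L, 201L),
                   end = c(50L, 150L, 260L), strand = "+",
                   gene_id = "g1", transcript_id = "t1")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  gr <- GenomicRanges::GRanges(ex$contig,
                               IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand, type = "exon",
                               gene_id = ex$gene_id,
                               transcript_id = ex$transcript_id)
  rtracklayer::export(gr, gtf, format = "gtf")
  got <- load_annotation(gtf)
  expect_equal(got[c("contig", "start", "end")], ex[c("contig", "start",
                                                      "end")])
  expect_equal(got$exon_rank, 1:3)
  # BED12: blockCount 3 implies 2 introns with block-derived coordinates
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t260\tg1|t1\t0\t+\t10\t260\t0\t3\t40,50,60\t0,90,190",
             bed)
  gotb <- load_annotation(bed)
  expect_equal(gotb$start, c(11L, 101L, 201L))
  expect_equal(gotb$end, c(50L, 150L, 260L))
  irb <- derive_introns(gotb)
  expect_equal(irb$start, c(51L, 151L))
  expect_equal(irb$end, c(100L, 200L))
})

test_that("annotation validation rejects malformed transcripts", {
  bad <- data.frame(contig = "c", start = c(1L, 50L), end = c(100L, 200L),
                    strand = "+", gene_id = "g", transcript_id = "t")
  expect_error(rslariat:::validate_exons(bad), "overlapping")
  bad2 <- data.frame(contig = c("c1", "c2"), start = c(1L, 300L),
                     end = c(100L, 400L), strand = "+", gene_id = "g",
                     transcript_id = "t")
  expect_error(rslariat:::validate_exons(bad2), "spans contigs")
})

test_that("constitutive introns require presence in every transcript", {
  mk <- function(tx, starts, ends) {
    data.frame(contig = "c", start = starts, end = ends, strand = "+",
               gene_id = "g", transcript_id = tx)
  }
  # two transcripts share intron A [101,200]; only t1 has intron B [301,400]
  ex <- rbind(mk("t1", c(1L, 201L, 401L), c(100L, 300L, 500L)),
              mk("t2", c(1L, 201L), c(100L, 500L)))
  ci <- constitutive_introns(rslariat:::validate_exons(ex))
  expect_equal(nrow(ci), 1L)
  expect_equal(c(ci$start, ci$end), c(101L, 200L))
  expect_true(all(ci$constitutive))
  # a single-transcript gene keeps all its introns
  ci1 <- constitutive_introns(rslariat:::validate_exons(
    mk("t1", c(1L, 201L, 401L), c(100L, 300L, 500L))))
  expect_equal(nrow(ci1), 2L)
  # no shared introns at all
  ex0 <- rbind(mk("t1", c(1L, 201L), c(100L, 300L)),
               mk("t2", c(1L, 151L), c(90L, 300L)))
  expect_equal(nrow(constitutive_introns(rslariat:::validate_exons(ex0))),
               0L)
})

test_that("internal and cassette exon flags follow the all-transcripts rule", {
  fx <- cassette_fixture()
  ec <- internal_cassette_exons(fx$exons)
  mid <- ec[ec$start == 301L, ]
  expect_true(mid$is_internal)
  expect_true(mid$is_cassette)
  first <- ec[ec$start == 101L, ]
  expect_false(first$is_internal)
  # exon that is middle in one transcript but terminal in another is not
  # internal
  ex <- data.frame(contig = "c",
                   start = c(1L, 201L, 401L, 1L, 201L),
                   end = c(100L, 300L, 500L, 100L, 300L),
                   strand = "+", gene_id = "g",
                   transcript_id = c("t1", "t1", "t1", "t2", "t2"))
  ec2 <- internal_cassette_exons(rslariat:::validate_exons(ex))
  expect_false(ec2$is_internal[ec2$start == 201L])
  # constitutive middle exon: internal but not cassette
  ex3 <- data.frame(contig = "c",
                    start = rep(c(1L, 201L, 401L), 2),
                    end = rep(c(100L, 300L, 500L), 2),
                    strand = "+", gene_id = "g",
                    transcript_id = rep(c("t1", "t2"), each = 3))
  ec3 <- internal_cassette_exons(rslariat:::validate_exons(ex3))
  expect_true(ec3$is_internal[ec3$start == 201L])
  expect_false(ec3$is_cassette[ec3$start == 201L])
})

test_that("simulated intron boundaries read GT..AG in transcription order", {
  cfg <- sim_config(n_genes = 12L, n_rs_sites = 3L, n_duplicated_sites = 0L,
                    seed = 2L)
  sim <- simulate_genome(cfg)
  for (i in seq_len(nrow(sim$introns))) {
    intr <- sim$introns[i, ]
    s <- fetch_seq(sim$genome, intr$contig, intr$start, intr$end,
                   intr$strand)
    expect_identical(substr(s, 1, 2), "GT")
    expect_identical(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }
})
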