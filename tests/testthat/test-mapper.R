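# Split-read lariat mapping: head search, trimming, tail alignment with the
# branchpoint mismatch policy, branchpoint inference, and 1/k weights.

test_that("head mapping finds planted occurrences and rejects ambiguity", {
  fx <- junction_fixture(put_local = 1000L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  head1 <- j$head_seq[j$jclass == "conventional"]
  head2 <- j$head_seq[j$five_class == "RS"]
  set.seed(9)
  reads <- data.frame(
    read_id = c("mid", "at_start", "double"),
    seq = c(paste0(random_dna(30), head1, random_dna(50)),
            paste0(head1, random_dna(80)),
            paste0(random_dna(10), head1, random_dna(10), head2,
                   random_dna(20))))
  hits <- map_heads(j, reads)
  expect_equal(hits$offset[hits$read_id == "mid"], 31L)
  expect_equal(hits$offset[hits$read_id == "at_start"], 1L)
  expect_false("double" %in% hits$read_id)   # two distinct 5'ss regions
})

test_that("trimming enforces the 20-nt minimum mapped prefix", {
  seq <- strrep("A", 100)
  expect_equal(nchar(trim_read(seq, 31L)), 30L)
  expect_identical(trim_read(seq, 1L), NA_character_)   # empty prefix
  expect_identical(trim_read(seq, 20L), NA_character_)  # 19-nt prefix
  expect_equal(nchar(trim_read(seq, 21L)), 20L)
})

test_that("tail alignment allows only a single final-base mismatch", {
  fx <- junction_fixture(put_local = 1500L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  conv <- j[j$jclass == "conventional", ]
  tail_seq <- conv$tail_seq
  head_seq <- conv$head_seq
  prefix <- substr(tail_seq, 201, 230)       # ends at tail offset 230
  mk <- function(p) data.frame(read_id = "r", seq = paste0(p, head_seq,
                                                           strrep("A", 20)))
  clean <- map_tails(map_heads(j, mk(prefix)), j)
  clean <- clean[clean$junction_id == conv$junction_id, ]
  expect_equal(nrow(clean), 1L)
  expect_false(clean$bp_mismatch)
  expect_equal(clean$bp_to_3ss, 250L - 230L)
  # substituting the final prefix base flags the branchpoint mismatch
  pm <- prefix
  substr(pm, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(pm, 30, 30))[1]
  mm <- map_tails(map_heads(j, mk(pm)), j)
  mm <- mm[mm$junction_id == conv$junction_id, ]
  expect_equal(nrow(mm), 1L)
  expect_true(mm$bp_mismatch)
  expect_equal(mm$bp_to_3ss, clean$bp_to_3ss)
  # an internal mismatch is rejected outright
  pi <- prefix
  substr(pi, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(pi, 15, 15))[1]
  int <- map_tails(map_heads(j, mk(pi)), j)
  expect_equal(nrow(int[int$junction_id == conv$junction_id, ]), 0L)
})

test_that("branchpoint distance hits the boundary conventions", {
  fx <- junction_fixture(put_local = 1500L)
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  conv <- j[j$jclass == "conventional", ]
  mk_at <- function(end_off) {
    prefix <- substr(conv$tail_seq, end_off - 29L, end_off)
    data.frame(read_id = "r",
               seq = paste0(prefix, conv$head_seq, strrep("A", 20)))
  }
  # alignment ending at the last tail base: branchpoint distance 0
  r0 <- map_tails(map_heads(j, mk_at(250L)), j)
  r0 <- r0[r0$junction_id == conv$junction_id, ]
  expect_equal(r0$bp_to_3ss, 0L)
  # ending 25 short of the tail end: the canonical 25-nt offset
  r25 <- map_tails(map_heads(j, mk_at(225L)), j)
  r25 <- r25[r25$junction_id == conv$junction_id, ]
  expect_equal(r25$bp_to_3ss, 25L)
  expect_equal(r25$bp_pos, conv$three_pos - 25L)
})

test_that("minus-strand branchpoints mirror and match the reference base", {
  fx <- junction_fixture(put_local = 1000L, strand = "-")
  j <- build_junctions(fx$genome, fx$intron, fx$sites)
  conv <- j[j$jclass == "conventional", ]
  prefix <- substr(conv$tail_seq, 196, 225)
  reads <- data.frame(read_id = "r",
                      seq = paste0(prefix, conv$head_seq, strrep("A", 20)))
  got <- map_tails(map_heads(j, reads), j)
  got <- got[got$junction_id == conv$junction_id, ]
  expect_equal(got$bp_to_3ss, 25L)
  expect_equal(got$bp_pos, conv$three_pos + 25L)
  # the reference base under the branchpoint equals the last prefix base
  expect_identical(fetch_seq(fx$genome, "chr", got$bp_pos, got$bp_pos, "-"),
                   substr(prefix, 30, 30))
})

test_that("weights split evenly over ambiguous 3'ss resolutions", {
  base <- data.frame(read_id = "r1", junction_id = c("a", "b"),
                     gene_id = "g", five_pos = 100L, bp_pos = 500L,
                     jclass = "putative", bp_mismatch = TRUE)
  w2 <- assign_weights(base)
  expect_equal(w2$weight, c(0.5, 0.5))
  w1 <- assign_weights(base[1, ])
  expect_equal(w1$weight, 1)
  base4 <- do.call(rbind, lapply(letters[1:4], function(x) {
    transform(base[1, ], junction_id = x)
  }))
  w4 <- assign_weights(base4)
  expect_equal(w4$weight, rep(0.25, 4))
  expect_true(sum(w4$weight) == 1)
})

test_that("mapping inverts the simulated read constructor exactly", {
  fx <- errorfree_run()
  truth <- fx$sim$truth
  lar <- fx$lariats
  lt <- truth[truth$label %in% c("rs_lariat", "conventional_lariat"), ]
  # qualifying reads: single distinct head sequence present in the read
  heads <- unique(fx$sim$junctions$head_seq)
  seqs <- fx$sim$reads$seq[match(lt$read_id, fx$sim$reads$read_id)]
  n_heads <- vapply(seqs, function(s)
    sum(vapply(heads, function(h) grepl(h, s, fixed = TRUE), logical(1))),
    numeric(1))
  clean <- lt[n_heads == 1L, ]
  expect_gt(nrow(clean), 300L)
  m <- merge(clean, lar, by = "read_id", suffixes = c(".t", ".m"))
  # every clean-head read is recovered, with the exact planted pair among
  # its (possibly weight-split) resolutions
  expect_setequal(unique(m$read_id), clean$read_id)
  agree <- tapply(m$five_pos.t == m$five_pos.m & m$bp_pos.t == m$bp_pos.m,
                  m$read_id, any)
  expect_true(all(agree))
})

test_that("per-read weight groups always sum to one in a full run", {
  fx <- errorfree_run()
  lar <- fx$lariats
  sums <- tapply(lar$weight,
                 paste(lar$read_id, lar$five_pos, lar$bp_pos), sum)
  expect_true(all(sums == 1))
})
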