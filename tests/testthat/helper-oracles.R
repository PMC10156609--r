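# Independent oracles used to pin the implementation. These deliberately
# re-derive each quantity from the definition by a different route than the
# package code takes.

# Brute-force motif scan: for every candidate G of a GT, check YAG
# immediately upstream and a >= min_pyr pyrimidine run ending 0..max_gap nt
# before the Y. Position-by-position loop, no shared code with the scanner.
oracle_scan_rs <- function(seq, min_pyr = 5L, max_gap = 4L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pyr <- ch %in% c("C", "T")
  pos <- integer()
  if (n < 2L) return(pos)
  for (p in seq_len(n - 1L)) {
    if (!(ch[p] == "G" && ch[p + 1L] == "T")) next
    y <- p - 3L
    if (y < 1L || !pyr[y] || ch[p - 2L] != "A" || ch[p - 1L] != "G") next
    hit <- FALSE
    for (g in 0:max_gap) {
      e <- y - g - 1L
      s <- e - min_pyr + 1L
      if (s < 1L) break
      if (all(pyr[s:e])) { hit <- TRUE; break }
    }
    if (hit) pos <- c(pos, p)
  }
  pos
}

# Regex route for the same motif: one lookahead pattern per gap width, GT
# position derived arithmetically from the match start.
oracle_scan_rs_regex <- function(seq, min_pyr = 5L, max_gap = 4L) {
  pos <- integer()
  for (g in 0:max_gap) {
    pat <- sprintf("(?=[CT]{%d}[ACGTN]{%d}[CT]AGGT)", min_pyr, g)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] != -1L) pos <- c(pos, as.integer(m) + min_pyr + g + 3L)
  }
  sort(unique(pos))
}

# Enumeration of the informative-read conditions over every loop position.
oracle_informative <- function(loop_len, read_len, min_region = 20L) {
  p <- seq_len(loop_len)
  d <- loop_len - p
  mean(d >= min_region & d + 1L <= read_len - min_region)
}

random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
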