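# The informative-read model.
#
# A lariat-derived read is informative only if it straddles the branchpoint
# with enough sequence on both sides to map: at least 20 nt of
# branchpoint-proximal sequence and at least 20 nt of 5'-splice-site
# sequence. For a read of length n starting at a uniformly random position
# of the lariat loop (intron start through branchpoint, with the branchpoint
# assumed 25 nt upstream of the 3' splice site), a start position p
# qualifies when it is at least 20 nt upstream of the branchpoint and no
# further from it than n - 20 - 1 nt, so the probability falls off
# hyperbolically with intron length — well approximated by a power law
# y = a * x^b.

#' Exact informative-read probability
#'
#' Closed form for the fraction of loop positions from which a read of
#' `read_len` nt is informative: `min(read_len - 2*min_region, loop_len -
#' min_region)` admissible positions (clamped to `[0, loop_len]`) out of
#' `loop_len`. Vectorised over `loop_len`.
#'
#' @param loop_len lariat loop length in nt (intron start through
#'   branchpoint).
#' @param read_len sequencing read length in nt.
#' @param min_region minimum mappable region per side (default 20).
#' @return probability in `[0, 1]`.
#' @export
informative_probability_exact <- function(loop_len, read_len,
                                          min_region = 20L) {
  stopifnot(all(loop_len >= 1))
  count <- pmin(read_len - 2L * min_region, loop_len - min_region)
  count <- pmax(0L, pmin(count, loop_len))
  count / loop_len
}

#' Monte-Carlo informative-read probability
#'
#' Estimates the same probability by sampling `n_samples` loop positions
#' uniformly with replacement and scoring the two mapping conditions
#' directly (at least `min_region` nt upstream of the branchpoint; close
#' enough that `min_region` nt remain beyond it within the read).
#'
#' @inheritParams informative_probability_exact
#' @param n_samples positions sampled per loop (default 1000).
#' @param seed optional RNG seed.
#' @return estimated probability.
#' @export
informative_probability_mc <- function(loop_len, read_len,
                                       n_samples = 1000L, seed = NULL,
                                       min_region = 20L) {
  stopifnot(loop_len >= 1)
  with_seed(seed, {
    p <- sample.int(loop_len, n_samples, replace = TRUE)
    d <- loop_len - p                       # distance to the branchpoint
    mean(d >= min_region & d + 1L <= read_len - min_region)
  })
}

#' Fit a power law y = a * x^b
#'
#' Least-squares fit on the log-log scale. Points with non-positive `y`
#' cannot enter the fit; their count is reported.
#'
#' @param lengths positive predictor values (intron lengths).
#' @param probabilities response values.
#' @return list with `a`, `b`, `n_used`, `n_dropped` and the underlying
#'   `lm` fit.
#' @export
fit_power_law <- function(lengths, probabilities) {
  stopifnot(length(lengths) == length(probabilities))
  ok <- lengths > 0 & probabilities > 0
  if (sum(ok) < 3L) stop("need at least 3 positive (x, y) pairs")
  fit <- lm(log(probabilities[ok]) ~ log(lengths[ok]))
  list(a = unname(exp(coef(fit)[1])), b = unname(coef(fit)[2]),
       n_used = sum(ok), n_dropped = sum(!ok), fit = fit)
}

#' Probability-weighted intron length distribution
#'
#' Returns, for each intron, its log10 length together with uniform
#' (unweighted) and detection-probability-weighted masses, both normalised
#' to sum to one. The weighted distribution is the length distribution of
#' lariats one expects to *observe* at a given read length under equal
#' expression; comparing the two shows how strongly short introns are
#' favoured by the mapping constraints.
#'
#' @param intron_lengths intron lengths in nt.
#' @param read_len read length in nt.
#' @param bp_offset assumed branchpoint offset upstream of the 3' splice
#'   site (default 25, the median U2 branchpoint position); introns no
#'   longer than `bp_offset` get probability 0.
#' @return data.frame with `length`, `log10_length`, `probability`,
#'   `w_unweighted`, `w_weighted`.
#' @export
weighted_length_distribution <- function(intron_lengths, read_len,
                                         bp_offset = 25L) {
  loop <- intron_lengths - bp_offset
  p <- ifelse(loop >= 1, informative_probability_exact(pmax(loop, 1L),
                                                       read_len), 0)
  if (sum(p) == 0) stop("no intron has a positive detection probability")
  data.frame(length = intron_lengths,
             log10_length = log10(intron_lengths),
             probability = p,
             w_unweighted = rep(1 / length(intron_lengths),
                                length(intron_lengths)),
             w_weighted = p / sum(p))
}
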