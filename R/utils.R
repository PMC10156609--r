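#' @importFrom stringi stri_reverse stri_sub stri_locate_all_fixed stri_count_fixed
#' @importFrom stats runif lm coef median rlnorm rbinom setNames
#' @importFrom utils head tail write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement of a plain character DNA string
#'
#' Vectorised over its input. Only A/C/G/T/N (uppercase) are handled, which is
#' the alphabet the package enforces at genome load time.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All seeded entry points funnel through here so a
# single seed determines every output byte.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample that never does the length-1 "sample from 1:n" surprise.
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
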