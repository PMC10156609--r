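# Motif scanning for recursive splice sites.
#
# The composite motif is a minimal U2 3' splice site joined to a minimal 5'
# splice site: a run of >= 5 consecutive pyrimidines, then 0-4 arbitrary
# bases, then YAG, then GT. The reported position is the G of the GT (the
# first base of the reconstituted 5' splice site); the site acting as a 3'
# splice site ends one base earlier, at the G of the YAG.

# Shared scanner: YAG candidates anchored on a fixed-string search, with a
# pyrimidine-run-length array for the tract check. `require_gt` adds the GT
# that turns a cryptic 3'ss into a full recursive-site motif.
scan_pyr_yag <- function(seq, require_gt, min_pyr = 5L, max_gap = 4L) {
  n <- nchar(seq)
  empty <- data.frame(pos = integer(), motif_start = integer(),
                      motif_end = integer())
  if (n < min_pyr + 3L + if (require_gt) 2L else 0L) return(empty)
  anchor <- if (require_gt) "AGGT" else "AG"
  loc <- stringi::stri_locate_all_fixed(seq, anchor)[[1]]
  if (is.na(loc[1, 1])) return(empty)
  y <- loc[, 1] - 1L                       # candidate Y of YAG
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pyr <- ch == "C" | ch == "T"
  y <- y[y >= min_pyr + 1L & pyr[pmax(y, 1L)]]
  if (!length(y)) return(empty)
  # runlen[i] = length of the pyrimidine run ending at position i
  idx <- seq_len(n)
  runlen <- idx - cummax(ifelse(!pyr, idx, 0L))
  res <- lapply(y, function(yp) {
    for (g in 0:max_gap) {
      tract_end <- yp - g - 1L
      if (tract_end < min_pyr) break
      if (runlen[tract_end] >= min_pyr) {
        return(c(pos = yp + 3L,
                 motif_start = tract_end - runlen[tract_end] + 1L,
                 motif_end = yp + 2L + if (require_gt) 2L else 0L))
      }
    }
    NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  out <- as.data.frame(res)
  out[order(out$pos), , drop = FALSE]
}

#' Scan a sequence for recursive splice-site motifs
#'
#' Finds every position where a run of at least five consecutive pyrimidines
#' ends 0-4 nt upstream of a YAG that is immediately followed by GT. The
#' input must already be in transcription order (minus-strand introns are
#' reverse-complemented by the caller). N never matches any motif position.
#'
#' @param seq a single nucleotide string over A/C/G/T/N.
#' @param min_pyr minimum pyrimidine-run length (default 5).
#' @param max_gap maximum gap between the run and the YAG (default 4).
#' @return data.frame with `pos` (1-based index of the G of the GT),
#'   `motif_start`, `motif_end` (span of the full match, including the
#'   maximal pyrimidine run).
#' @export
scan_rs_motif <- function(seq, min_pyr = 5L, max_gap = 4L) {
  out <- scan_pyr_yag(seq, require_gt = TRUE, min_pyr = min_pyr,
                      max_gap = max_gap)
  rownames(out) <- NULL
  out
}

#' Scan for cryptic 3' splice-site motifs
#'
#' Same motif as [scan_rs_motif()] but without the GT requirement (a
#' polypyrimidine tract, a 0-4 nt gap, and YAG). Used to exclude decoy sites
#' that lie within mapping range of a position that could act as a cryptic
#' 3' splice site. `pos` here is the base immediately after the YAG, i.e.
#' where a reconstituted 5'ss would start, matching the coordinate
#' convention of [scan_rs_motif()].
#'
#' @inheritParams scan_rs_motif
#' @return data.frame as in [scan_rs_motif()].
#' @export
scan_cryptic_3ss <- function(seq, min_pyr = 5L, max_gap = 4L) {
  out <- scan_pyr_yag(seq, require_gt = FALSE, min_pyr = min_pyr,
                      max_gap = max_gap)
  rownames(out) <- NULL
  out
}
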