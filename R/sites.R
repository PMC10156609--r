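# Candidate and decoy recursive-splice-site generation.

#' Generate filtered random decoy sites for one intron
#'
#' Draws `n_per_site` random intronic positions per putative site (uniformly,
#' without replacement), then removes candidates that could plausibly carry
#' genuine splicing signal: those with a GT at the position, and those within
#' `window` nt of a cryptic 3' splice-site motif, of a putative recursive
#' site, or of the intron's annotated 3' splice site. Decoys are *not*
#' redrawn after filtering, so the surviving count is typically below
#' `n_per_site` per putative site. Surviving decoys carry no splice-like
#' context, which is what makes them usable for empirical FDR estimation.
#'
#' @param seq intron sequence in transcription order.
#' @param putative_pos integer vector of putative site positions (local,
#'   1-based, the G of the GT) within `seq`; must be non-empty.
#' @param n_per_site decoys drawn per putative site (default 5).
#' @param window exclusion distance in nt, the tail mapping range
#'   (default 250).
#' @param seed optional RNG seed; when `NULL` the current RNG stream is used
#'   (callers that loop over introns seed once outside).
#' @return sorted integer vector of surviving decoy positions (local,
#'   1-based), possibly empty.
#' @export
generate_decoys <- function(seq, putative_pos, n_per_site = 5L,
                            window = 250L, seed = NULL) {
  stopifnot(length(putative_pos) >= 1L)
  with_seed(seed, {
    L <- nchar(seq)
    universe <- seq_len(L)[-c(1L, L)]          # interior positions only
    if (!length(universe)) return(integer())
    n_draw <- min(length(universe), n_per_site * length(putative_pos))
    cand <- sort(sample_safe(universe, n_draw))
    # adjacent GT: the candidate could act as a reconstituted 5'ss
    gt <- stringi::stri_sub(seq, cand, cand + 1L) == "GT"
    cand <- cand[!gt]
    if (!length(cand)) return(integer())
    cryptic <- scan_cryptic_3ss(seq)$pos
    excl <- c(cryptic, putative_pos, L + 1L)   # L+1 = position after the
    # annotated 3'ss, same convention as site positions (5'ss-start side)
    near <- vapply(cand, function(p) any(abs(p - excl) <= window), logical(1))
    cand[!near]
  })
}

#' Discover putative and decoy recursive splice sites in introns
#'
#' Scans every intron's transcription-order sequence with [scan_rs_motif()]
#' and pairs each putative site with seeded random decoys via
#' [generate_decoys()]. Positions are reported both locally (1-based within
#' the intron, transcription order) and genomically (forward strand).
#'
#' @param genome genome object.
#' @param introns intron table with `intron_id` (e.g. from
#'   [constitutive_introns()]).
#' @param n_decoys_per_site decoys drawn per putative site.
#' @param window decoy exclusion window in nt.
#' @param seed integer seed; fully determines the decoy draw.
#' @return data.frame with `site_id`, `intron_id`, `gene_id`, `contig`,
#'   `strand`, `kind` (`"putative"`/`"decoy"`), `local_pos`, `pos`
#'   (genomic coordinate of the first base of the reconstituted 5'ss GT, in
#'   transcription order), `motif_start`, `motif_end` (local; NA for
#'   decoys).
#' @export
discover_sites <- function(genome, introns, n_decoys_per_site = 5L,
                           window = 250L, seed = 1L) {
  with_seed(seed, {
    out <- vector("list", nrow(introns))
    for (i in seq_len(nrow(introns))) {
      intr <- introns[i, ]
      seq <- fetch_seq(genome, intr$contig, intr$start, intr$end, intr$strand)
      hits <- scan_rs_motif(seq)
      if (!nrow(hits)) next
      dec <- generate_decoys(seq, hits$pos, n_per_site = n_decoys_per_site,
                             window = window)
      loc <- c(hits$pos, dec)
      kind <- rep(c("putative", "decoy"), c(nrow(hits), length(dec)))
      out[[i]] <- data.frame(
        intron_id = intr$intron_id, gene_id = intr$gene_id,
        contig = intr$contig, strand = intr$strand, kind = kind,
        local_pos = loc,
        pos = local_to_genomic(loc, intr),
        motif_start = c(hits$motif_start, rep(NA_integer_, length(dec))),
        motif_end = c(hits$motif_end, rep(NA_integer_, length(dec))))
    }
    sites <- do.call(rbind, out)
    if (is.null(sites)) {
      sites <- data.frame(intron_id = character(), gene_id = character(),
                          contig = character(), strand = character(),
                          kind = character(), local_pos = integer(),
                          pos = integer(), motif_start = integer(),
                          motif_end = integer())
    }
    sites$site_id <- paste0(sites$intron_id, "|", sites$kind, "@", sites$pos)
    rownames(sites) <- NULL
    sites
  })
}

# Local (1-based, transcription order within an intron/feature) <-> genomic.
local_to_genomic <- function(local, feature) {
  if (feature$strand == "+") feature$start + local - 1L
  else feature$end - local + 1L
}

genomic_to_local <- function(pos, feature) {
  if (feature$strand == "+") pos - feature$start + 1L
  else feature$end - pos + 1L
}
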