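# Seeded simulator for recursive-splicing lariat detection.
#
# Emits a synthetic genome with GT..AG introns, planted recursive splice
# sites carrying the full discovery motif, optional planted repeat runs and
# duplicated mapped regions, and a read set with per-read truth labels:
# recursive lariats (inverted reads with a reverse-transcriptase mismatch at
# the branchpoint), conventional lariats, linear mRNA / pre-mRNA / genomic
# background, and self-primed circularisation artifacts. One seed
# determines every output byte.

#' Simulator configuration
#'
#' Defaults describe the study conditions the package is validated under:
#' 200 genes, 50 cleanly planted recursive sites, 100-nt reads, 10 lariat
#' reads per junction, a 0.3 reverse-transcriptase mismatch probability at
#' the branchpoint, and all artifact classes enabled.
#'
#' @param n_genes number of genes (one contig each).
#' @param n_rs_sites cleanly planted recursive splice sites.
#' @param n_duplicated_sites extra planted sites whose 5'ss 20-mer is also
#'   copied elsewhere in the genome (uniqueness-filter confounders).
#' @param exon_meanlog,exon_sdlog,intron_meanlog,intron_sdlog log-normal
#'   length parameters for exons and introns.
#' @param flank_len intergenic flank per contig side.
#' @param read_len read length in nt.
#' @param reads_per_junction lariat reads generated per planted junction.
#' @param conventional_frac fraction of introns also producing conventional
#'   lariats.
#' @param conventional_reads conventional lariat reads per such intron.
#' @param bp_mismatch_prob probability of the RT mismatch at the
#'   branchpoint.
#' @param bp_offset_range inclusive range of planted branchpoint offsets
#'   upstream of the 3'-acting site.
#' @param seq_error_rate uniform per-base substitution error rate.
#' @param n_background_reads linear background reads (mRNA, pre-mRNA,
#'   genomic in 2:2:1 proportions).
#' @param n_self_primed target number of self-primed artifact reads.
#' @param n_dup_segments intronic segments copied elsewhere in the genome
#'   (segmental-duplication confounders; decoys falling inside them are
#'   non-unique, like the duplicated planted sites).
#' @param dup_segment_len length of each duplicated segment (nt).
#' @param chimera_junctions_per_class decoy junctions receiving chimeric
#'   artifact reads, per artifact flavour (near-splice-site,
#'   duplicated-region, repeat-edge, out-of-window branchpoint). Chimeric
#'   template-switching products respect none of the biological constraints
#'   genuine lariats satisfy; each flavour violates one of them.
#' @param chimera_reads reads per chimeric junction.
#' @param chimera_bp_mismatch_prob probability that a chimeric read carries
#'   a junction-point mismatch (template switching is itself error-prone).
#' @param n_repeat_regions planted simple-repeat runs.
#' @param n_decoys_per_site decoys drawn per putative site.
#' @param base_probs composition of background sequence over A/C/G/T
#'   (pyrimidines mildly suppressed to keep the spurious motif density low
#'   but non-zero).
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L, n_rs_sites = 50L,
                       n_duplicated_sites = 3L,
                       exon_meanlog = log(150), exon_sdlog = 0.25,
                       intron_meanlog = log(1200), intron_sdlog = 0.5,
                       flank_len = 300L, read_len = 100L,
                       reads_per_junction = 10L,
                       conventional_frac = 0.25, conventional_reads = 5L,
                       bp_mismatch_prob = 0.3,
                       bp_offset_range = c(10L, 60L),
                       seq_error_rate = 0.001,
                       n_background_reads = 1500L, n_self_primed = 60L,
                       n_dup_segments = 12L, dup_segment_len = 1500L,
                       chimera_junctions_per_class = 8L, chimera_reads = 3L,
                       chimera_bp_mismatch_prob = 0.5,
                       n_repeat_regions = 20L, n_decoys_per_site = 5L,
                       base_probs = c(A = 0.28, C = 0.22, G = 0.28,
                                      T = 0.22),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$bp_mismatch_prob >= 0, cfg$bp_mismatch_prob <= 1,
            cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1,
            abs(sum(cfg$base_probs) - 1) < 1e-9)
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Overwrite `str` starting at transcription-order position `local` of
# `feature` (list/row with start, end, strand) inside the forward-strand
# contig sequence `contig_seq`.
write_local <- function(contig_seq, feature, local, str) {
  w <- nchar(str)
  if (feature$strand == "+") {
    g <- feature$start + local - 1L
    stringi::stri_sub(contig_seq, g, g + w - 1L) <- str
  } else {
    g_end <- feature$end - local + 1L
    stringi::stri_sub(contig_seq, g_end - w + 1L, g_end) <- revcomp(str)
  }
  contig_seq
}

#' Simulate a genome with planted recursive splice sites
#'
#' Builds one contig per gene (single-transcript genes, so every intron is
#' constitutive), with canonical GT..AG intron boundaries, and plants
#' `n_rs_sites` clean recursive-site motifs plus `n_duplicated_sites`
#' confounded ones, `n_repeat_regions` simple-repeat runs, and records the
#' truth.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `exons`, `introns` (constitutive, with
#'   `intron_id`), `sites_truth`, `repeats`, `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  if (exp(cfg$intron_meanlog) < 50)
    stop("infeasible config: introns too short to carry the motif")
  with_seed(cfg$seed, {
    contigs <- character(cfg$n_genes)
    names(contigs) <- sprintf("ctg%03d", seq_len(cfg$n_genes))
    exon_rows <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) {
      n_ex <- sample(2:4, 1L)
      ex_len <- pmin(pmax(round(rlnorm(n_ex, cfg$exon_meanlog,
                                       cfg$exon_sdlog)), 60L), 400L)
      in_len <- pmin(pmax(round(rlnorm(n_ex - 1L, cfg$intron_meanlog,
                                       cfg$intron_sdlog)), 200L), 8000L)
      strand <- sample(c("+", "-"), 1L)
      total <- sum(ex_len) + sum(in_len) + 2L * cfg$flank_len
      seq <- rand_seq(total, cfg$base_probs)
      pos <- cfg$flank_len + 1L
      es <- integer(n_ex); ee <- integer(n_ex)
      for (i in seq_len(n_ex)) {
        es[i] <- pos; ee[i] <- pos + ex_len[i] - 1L
        pos <- ee[i] + 1L
        if (i < n_ex) pos <- pos + in_len[i]
      }
      # canonical splice boundaries, transcription order GT..AG
      for (i in seq_len(n_ex - 1L)) {
        intr <- list(start = ee[i] + 1L, end = es[i + 1L] - 1L,
                     strand = strand)
        seq <- write_local(seq, intr, 1L, "GT")
        seq <- write_local(seq, intr, in_len[i] - 1L, "AG")
      }
      contigs[g] <- seq
      exon_rows[[g]] <- data.frame(contig = names(contigs)[g], start = es,
                                   end = ee, strand = strand,
                                   gene_id = sprintf("gene%03d", g),
                                   transcript_id = sprintf("tx%03d", g))
    }
    exons <- validate_exons(do.call(rbind, exon_rows))
    genome_chr <- contigs

    introns <- constitutive_introns(exons)
    margin <- 300L
    eligible <- which(introns$length >= 2L * margin + 100L)
    n_plant <- cfg$n_rs_sites + cfg$n_duplicated_sites
    if (length(eligible) < n_plant)
      stop("infeasible config: not enough long introns to plant ",
           n_plant, " sites")
    chosen <- sample_safe(eligible, n_plant)
    truth <- vector("list", n_plant)
    for (k in seq_len(n_plant)) {
      intr <- introns[chosen[k], ]
      L <- intr$length
      run <- sample(5:8, 1L)
      gap <- sample(0:4, 1L)
      motif <- paste0(
        paste(sample(c("C", "T"), run, TRUE), collapse = ""),
        if (gap > 0) rand_seq(gap, cfg$base_probs) else "",
        sample(c("C", "T"), 1L), "AG", "GT")
      local_pos <- sample((margin + 1L):(L - margin), 1L)  # the G of GT
      motif_start <- local_pos - (nchar(motif) - 2L)
      genome_chr[intr$contig] <- write_local(genome_chr[intr$contig], intr,
                                             motif_start, motif)
      truth[[k]] <- data.frame(
        intron_id = intr$intron_id, gene_id = intr$gene_id,
        contig = intr$contig, strand = intr$strand,
        local_pos = local_pos,
        pos = local_to_genomic(local_pos, intr),
        duplicated = k > cfg$n_rs_sites)
    }
    sites_truth <- do.call(rbind, truth)

    # duplicated-region confounders: copy the 20-mer at the site into the
    # downstream flank of a different contig
    dup <- which(sites_truth$duplicated)
    for (d in dup) {
      st <- sites_truth[d, ]
      intr <- introns[introns$intron_id == st$intron_id, ]
      kmer <- fetch_seq(as_genome(genome_chr), st$contig,
                        if (st$strand == "+") st$pos else st$pos - 19L,
                        if (st$strand == "+") st$pos + 19L else st$pos,
                        st$strand)
      other <- sample_safe(setdiff(names(genome_chr), st$contig), 1L)
      tgt <- nchar(genome_chr[other]) - cfg$flank_len + 50L
      stringi::stri_sub(genome_chr[other], tgt, tgt + 19L) <- kmer
    }

    # segmental-duplication confounders: intronic windows copied onto
    # dedicated contigs, so candidate sites and decoys inside them fail the
    # genomic-uniqueness criterion. Duplications only confound the decoy
    # side where decoys can actually land (inside an intron that carries a
    # motif hit, away from every cryptic-splicing exclusion zone), so the
    # window with the largest decoy-eligible coverage is copied.
    dup_rows <- list()
    free <- setdiff(seq_len(nrow(introns)), chosen)
    seg_introns <- integer()
    seg_cand <- sample_safe(free, length(free))
    tmp_genome <- as_genome(genome_chr)
    for (ii in seg_cand) {
      if (length(seg_introns) >= cfg$n_dup_segments) break
      intr <- introns[ii, ]
      L <- intr$length
      if (L < cfg$dup_segment_len + 400L) next
      iseq <- fetch_seq(tmp_genome, intr$contig, intr$start, intr$end,
                        intr$strand)
      put <- scan_rs_motif(iseq)$pos
      if (!length(put)) next                # no motif hit, no decoys here
      excl <- c(scan_cryptic_3ss(iseq)$pos, put, L + 1L)
      ok <- rep(TRUE, L)
      for (e in excl) {
        ok[max(1L, e - 250L):min(L, e + 250L)] <- FALSE
      }
      cum <- cumsum(ok)
      w <- cfg$dup_segment_len
      starts <- seq_len(L - w + 1L)
      cover <- cum[starts + w - 1L] - c(0L, cum)[starts]
      best <- which.max(cover)
      if (cover[best] < 100L) next          # too little decoy-eligible space
      si <- length(seg_introns) + 1L
      seg_introns <- c(seg_introns, ii)
      g1 <- local_to_genomic(best, intr)
      g2 <- local_to_genomic(best + w - 1L, intr)
      seg <- stringi::stri_sub(genome_chr[intr$contig], min(g1, g2),
                               max(g1, g2))
      nm <- sprintf("dup%02d", si)
      genome_chr[nm] <- paste0(rand_seq(50L, cfg$base_probs), seg,
                               rand_seq(50L, cfg$base_probs))
      dup_rows[[si]] <- data.frame(contig = intr$contig,
                                   start = min(g1, g2), end = max(g1, g2),
                                   intron_id = intr$intron_id)
    }
    dup_segments <- if (length(dup_rows)) do.call(rbind, dup_rows) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 intron_id = character())

    # simple-repeat runs planted mid-intron, away from planted sites
    rep_rows <- list()
    rep_introns <- sample_safe(setdiff(free, seg_introns),
                               min(cfg$n_repeat_regions,
                                   length(setdiff(free, seg_introns))))
    for (ri in rep_introns) {
      intr <- introns[ri, ]
      if (intr$length < 300L) next
      unit <- sample(c("CT", "AT", "AG", "CA"), 1L)
      run <- strrep(unit, 15L)
      local <- sample(100L:(intr$length - 100L - nchar(run)), 1L)
      genome_chr[intr$contig] <- write_local(genome_chr[intr$contig], intr,
                                             local, run)
      g1 <- local_to_genomic(local, intr)
      g2 <- local_to_genomic(local + nchar(run) - 1L, intr)
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(contig = intr$contig, start = min(g1, g2),
                   end = max(g1, g2), class = "Simple_repeat")
    }
    repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 class = character())

    list(genome = as_genome(genome_chr), exons = exons, introns = introns,
         sites_truth = sites_truth, repeats = repeats,
         dup_segments = dup_segments, config = cfg)
  })
}

# Extended transcription-order intron sequence with `pad` extra bases on
# both sides (local intron position x sits at string index x + pad).
intron_ext_seq <- function(genome, intr, pad = 10L) {
  fetch_seq(genome, intr$contig, intr$start - pad, intr$end + pad,
            intr$strand)
}

# One lariat-type read for a junction: prefix ending at the branchpoint
# followed by the sequence from the 5' splice site onward, in the local
# coordinates of `ext` (padded by `pad`).
construct_lariat_read <- function(ext, pad, five_local, bp_local, read_len,
                                  prefix_len, rt_mismatch) {
  pre <- stringi::stri_sub(ext, bp_local - prefix_len + 1L + pad,
                           bp_local + pad)
  if (rt_mismatch) {
    old <- stringi::stri_sub(pre, prefix_len, prefix_len)
    stringi::stri_sub(pre, prefix_len, prefix_len) <-
      sample_safe(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  suf_len <- read_len - prefix_len
  suf <- stringi::stri_sub(ext, five_local + pad,
                           five_local + pad + suf_len - 1L)
  paste0(pre, suf)
}

# 5-mer ending at (and including) local position x of `ext`, vs the 5-mer
# just upstream of the junction's 5'ss; the self-primed filter drops reads
# whose two 5-mers agree.
selfprime_match <- function(ext, pad, five_local, bp_local, k = 5L) {
  bp5 <- stringi::stri_sub(ext, bp_local - k + 1L + pad, bp_local + pad)
  up5 <- stringi::stri_sub(ext, five_local - k + pad, five_local - 1L + pad)
  bp5 == up5
}

#' Simulate reads with truth labels
#'
#' Generates recursive and conventional lariat reads (inverted order across
#' the branchpoint, RT mismatch with probability `bp_mismatch_prob`),
#' self-primed circularisation artifacts (placed exactly where the
#' branchpoint-inclusive 5-mer equals the 5-mer upstream of the 5' splice
#' site, on putative and decoy junctions alike), and linear mRNA, pre-mRNA
#' and genomic background, then applies uniform sequencing errors. Planted
#' branchpoints for genuine lariats are chosen to avoid the self-primed
#' signature, since such lariats would be indistinguishable from the
#' artifact by design.
#'
#' Decoy positions are obtained from the package's own seeded
#' [discover_sites()], so artifact reads land on the same decoy junctions a
#' pipeline run under the same seed will construct.
#'
#' @param sim output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list with `reads` (read_id, seq), `truth` (per-read label and
#'   planted coordinates), `sites` (discovery table), `junctions`.
#' @export
simulate_reads <- function(sim, config = sim$config) {
  cfg <- config
  genome <- sim$genome
  introns <- sim$introns
  sites <- discover_sites(genome, introns,
                          n_decoys_per_site = cfg$n_decoys_per_site,
                          seed = cfg$seed)
  junctions <- build_junctions(genome, introns, sites)
  pad <- 10L
  lo <- cfg$bp_offset_range[1]; hi <- cfg$bp_offset_range[2]

  with_seed(cfg$seed + 1L, {
    reads <- character(); labels <- character()
    t_junction <- character(); t_five <- integer(); t_bp <- integer()
    t_prefix <- integer(); t_mm <- logical(); t_ac <- character()
    emit <- function(seq, label, junction_id = NA_character_,
                     five_pos = NA_integer_, bp_pos = NA_integer_,
                     prefix_len = NA_integer_, mm = NA,
                     aclass = NA_character_) {
      reads[length(reads) + 1L] <<- seq
      labels[length(labels) + 1L] <<- label
      t_junction[length(t_junction) + 1L] <<- junction_id
      t_five[length(t_five) + 1L] <<- five_pos
      t_bp[length(t_bp) + 1L] <<- bp_pos
      t_prefix[length(t_prefix) + 1L] <<- prefix_len
      t_mm[length(t_mm) + 1L] <<- mm
      t_ac[length(t_ac) + 1L] <<- aclass
    }

    intron_by_id <- introns[match(junctions$intron_id, introns$intron_id), ]
    ext_cache <- new.env(parent = emptyenv())
    get_ext <- function(intron_id) {
      if (is.null(ext_cache[[intron_id]])) {
        intr <- introns[introns$intron_id == intron_id, ]
        ext_cache[[intron_id]] <- intron_ext_seq(genome, intr, pad)
      }
      ext_cache[[intron_id]]
    }
    jn_local <- function(j) {
      intr <- introns[introns$intron_id == j$intron_id, ]
      list(intr = intr, ext = get_ext(j$intron_id))
    }

    # pick a branchpoint offset in [lo, hi] for a junction; `want_match`
    # selects self-primed-signature positions (for artifacts) or clean
    # positions (for genuine lariats). NA if none qualifies.
    pick_bp <- function(j, want_match) {
      x <- jn_local(j)
      offs <- sample(lo:hi)
      for (o in offs) {
        bp_local <- j$three_local - o
        if (bp_local - j$five_local + 1L < 21L) next
        m <- selfprime_match(x$ext, pad, j$five_local, bp_local)
        if (m == want_match) return(bp_local)
      }
      NA_integer_
    }

    emit_lariat_reads <- function(j, label, n, bp_local,
                                  mismatch_prob = cfg$bp_mismatch_prob,
                                  aclass = NA_character_) {
      x <- jn_local(j)
      loop <- bp_local - j$five_local + 1L
      max_pre <- min(cfg$read_len - 20L, loop, j$tail_len -
                       (j$three_local - bp_local))
      if (max_pre < 20L) return(invisible(0L))
      bp_pos <- local_to_genomic(bp_local, x$intr)
      for (r in seq_len(n)) {
        pl <- sample(20:max_pre, 1L)
        mm <- runif(1) < mismatch_prob
        seq <- construct_lariat_read(x$ext, pad, j$five_local, bp_local,
                                     cfg$read_len, pl, mm)
        emit(seq, label, j$junction_id, j$five_pos, bp_pos, pl, mm, aclass)
      }
      invisible(n)
    }

    # --- recursive lariats on planted sites -------------------------------
    planted_pos <- sim$sites_truth$pos
    for (k in seq_len(nrow(sim$sites_truth))) {
      st <- sim$sites_truth[k, ]
      # junctions where this site acts as 3'ss (junction ends at pos - 1 in
      # transcription order) or as 5'ss (junction starts at pos)
      as3 <- junctions$jclass == "putative" &
        junctions$intron_id == st$intron_id &
        junctions$three_class == "RS" &
        junctions$three_pos == ifelse(st$strand == "+", st$pos - 1L,
                                      st$pos + 1L) &
        junctions$five_class == "annotated"
      as5 <- junctions$jclass == "putative" &
        junctions$intron_id == st$intron_id &
        junctions$five_class == "RS" & junctions$five_pos == st$pos &
        junctions$three_class == "annotated"
      for (ji in which(as3 | as5)) {
        j <- junctions[ji, ]
        bp_local <- pick_bp(j, want_match = FALSE)
        if (is.na(bp_local)) next
        emit_lariat_reads(j, "rs_lariat", cfg$reads_per_junction, bp_local)
      }
    }

    # --- conventional lariats ---------------------------------------------
    conv <- junctions[junctions$jclass == "conventional", , drop = FALSE]
    n_conv <- round(cfg$conventional_frac * nrow(conv))
    for (ji in sample_safe(seq_len(nrow(conv)), n_conv)) {
      j <- conv[ji, ]
      bp_local <- pick_bp(j, want_match = FALSE)
      if (is.na(bp_local)) next
      emit_lariat_reads(j, "conventional_lariat", cfg$conventional_reads,
                        bp_local)
    }

    # --- self-primed artifacts --------------------------------------------
    cand <- junctions[junctions$jclass %in% c("putative", "decoy"), ,
                      drop = FALSE]
    n_art <- 0L
    for (ji in sample_safe(seq_len(nrow(cand)), nrow(cand))) {
      if (n_art >= cfg$n_self_primed) break
      j <- cand[ji, ]
      bp_local <- pick_bp(j, want_match = TRUE)
      if (is.na(bp_local)) next
      n <- min(3L, cfg$n_self_primed - n_art)
      emit_lariat_reads(j, "self_primed_artifact", n, bp_local,
                        mismatch_prob = cfg$chimera_bp_mismatch_prob,
                        aclass = "self_primed")
      n_art <- n_art + n
    }

    # --- chimeric template-switching artifacts on decoy junctions ---------
    # Template switching respects none of the constraints genuine lariats
    # satisfy; each flavour violates one of them, and each affects decoys
    # exactly as it would putative sites (the premise of decoy-based FDR).
    dec <- junctions[junctions$jclass == "decoy", , drop = FALSE]
    n_cls <- cfg$chimera_junctions_per_class
    chim <- function(j, bp_local, flavour) {
      emit_lariat_reads(j, "chimera_artifact", cfg$chimera_reads, bp_local,
                        mismatch_prob = cfg$chimera_bp_mismatch_prob,
                        aclass = flavour)
    }
    if (n_cls > 0L && nrow(dec)) {
      # (i) decoy-as-5'ss within the proximity window of the annotated 5'ss
      near <- dec[dec$five_class == "decoy" & dec$five_local <= 101L, ,
                  drop = FALSE]
      for (ji in sample_safe(seq_len(nrow(near)), min(n_cls, nrow(near)))) {
        j <- near[ji, ]
        bp_local <- pick_bp(j, want_match = FALSE)
        if (!is.na(bp_local)) chim(j, bp_local, "near_ss")
      }
      # (ii) decoy 5'ss 20-mer inside a duplicated genomic segment
      if (nrow(sim$dup_segments)) {
        d5 <- dec[dec$five_class == "decoy", , drop = FALSE]
        in_seg <- vapply(seq_len(nrow(d5)), function(i) {
          s <- sim$dup_segments[sim$dup_segments$contig == d5$contig[i], ,
                                drop = FALSE]
          if (!nrow(s)) return(FALSE)
          lo <- if (d5$strand[i] == "+") d5$five_pos[i] else
            d5$five_pos[i] - 19L
          any(s$start <= lo & s$end >= lo + 19L)
        }, logical(1))
        dseg <- d5[in_seg, , drop = FALSE]
        for (ji in sample_safe(seq_len(nrow(dseg)),
                               min(n_cls, nrow(dseg)))) {
          j <- dseg[ji, ]
          bp_local <- pick_bp(j, want_match = FALSE)
          if (!is.na(bp_local)) chim(j, bp_local, "dup_region")
        }
      }
      # (iii) branchpoint window grazing a planted repeat edge
      if (nrow(sim$repeats)) {
        pick_bp_repeat_edge <- function(j) {
          rr <- sim$repeats[sim$repeats$contig == j$contig, , drop = FALSE]
          if (!nrow(rr)) return(NA_integer_)
          intr <- introns[introns$intron_id == j$intron_id, ]
          for (o in sample(lo:hi)) {
            bp_local <- j$three_local - o
            if (bp_local - j$five_local + 1L < 21L) next
            bp_g <- local_to_genomic(bp_local, intr)
            win <- sort(c(bp_g, bp_g + if (intr$strand == "+") -19L
                          else 19L))
            ov <- pmax(0L, pmin(win[2], rr$end) -
                         pmax(win[1], rr$start) + 1L)
            if (any(ov >= 1L) && all(ov <= 6L)) return(bp_local)
          }
          NA_integer_
        }
        drep <- dec[dec$contig %in% sim$repeats$contig, , drop = FALSE]
        done <- 0L
        for (ji in sample_safe(seq_len(nrow(drep)), nrow(drep))) {
          if (done >= n_cls) break
          j <- drep[ji, ]
          bp_local <- pick_bp_repeat_edge(j)
          if (!is.na(bp_local)) {
            chim(j, bp_local, "repeat_edge")
            done <- done + 1L
          }
        }
      }
      # (iv) switch point outside the 10-60 nt branchpoint window of every
      # 3'-acting element reachable from the same 5' element (otherwise the
      # read is indistinguishable from a genuine lariat of a sibling
      # junction and legitimately resolves there)
      sib3 <- split(junctions$three_local,
                    paste(junctions$intron_id, junctions$five_pos))
      pick_bp_out <- function(j) {
        t3s <- sib3[[paste(j$intron_id, j$five_pos)]]
        for (o in sample(c(5:9, 61:120))) {
          bp_local <- j$three_local - o
          if (bp_local - j$five_local + 1L < 21L) next
          if (j$tail_len - o < 20L) next
          d <- t3s - bp_local
          if (any(d >= lo & d <= hi)) next
          return(bp_local)
        }
        NA_integer_
      }
      done <- 0L
      for (ji in sample_safe(seq_len(nrow(dec)), nrow(dec))) {
        if (done >= n_cls) break
        j <- dec[ji, ]
        bp_local <- pick_bp_out(j)
        if (!is.na(bp_local)) {
          chim(j, bp_local, "out_of_window")
          done <- done + 1L
        }
      }
    }

    # --- linear background -------------------------------------------------
    tx <- transcript_sequences(genome, sim$exons)
    tx <- tx[nchar(tx) >= cfg$read_len]
    n_bg <- cfg$n_background_reads
    n_mrna <- round(0.4 * n_bg); n_pre <- round(0.4 * n_bg)
    n_gen <- n_bg - n_mrna - n_pre
    draw_sub <- function(pool, n, label) {
      src <- sample_safe(seq_along(pool), n, replace = TRUE)
      for (i in src) {
        s <- sample.int(nchar(pool[i]) - cfg$read_len + 1L, 1L)
        emit(stringi::stri_sub(pool[i], s, s + cfg$read_len - 1L), label)
      }
    }
    gene_spans <- vapply(split(sim$exons, sim$exons$gene_id), function(ex) {
      fetch_seq(genome, ex$contig[1], min(ex$start), max(ex$end),
                ex$strand[1])
    }, character(1))
    draw_sub(tx, n_mrna, "mrna")
    draw_sub(gene_spans[nchar(gene_spans) >= cfg$read_len], n_pre,
             "pre_mrna")
    draw_sub(unclass(genome), n_gen, "genomic")

    # --- sequencing errors --------------------------------------------------
    n_err_total <- 0L
    if (cfg$seq_error_rate > 0) {
      for (i in seq_along(reads)) {
        L <- nchar(reads[i])
        ne <- rbinom(1L, L, cfg$seq_error_rate)
        if (ne == 0L) next
        n_err_total <- n_err_total + ne
        at <- sample.int(L, ne)
        for (p in at) {
          old <- stringi::stri_sub(reads[i], p, p)
          stringi::stri_sub(reads[i], p, p) <-
            sample_safe(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }

    ids <- sprintf("read%06d", seq_along(reads))
    list(reads = data.frame(read_id = ids, seq = reads),
         truth = data.frame(read_id = ids, label = labels,
                            junction_id = t_junction, five_pos = t_five,
                            bp_pos = t_bp, prefix_len = t_prefix,
                            rt_mismatch = t_mm, artifact_class = t_ac),
         sites = sites, junctions = junctions,
         n_seq_errors = n_err_total)
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulate_genome()] then [simulate_reads()] under one seed.
#'
#' @param config a [sim_config()].
#' @return list combining both outputs.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  rd <- simulate_reads(sim, config)
  c(sim, rd)
}

#' Write a simulated dataset to standard formats
#'
#' Emits `genome.fa`, `annotation.gtf`, `repeats.bed`, `reads.fastq`,
#' `truth_reads.tsv` and `truth_sites.tsv` under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  ex <- sim$exons
  gr <- GenomicRanges::GRanges(ex$contig, IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand, type = "exon",
                               gene_id = ex$gene_id,
                               transcript_id = ex$transcript_id)
  rtracklayer::export(gr, file.path(dir, "annotation.gtf"), format = "gtf")
  if (nrow(sim$repeats)) {
    write_bed6(data.frame(contig = sim$repeats$contig,
                          start = sim$repeats$start, end = sim$repeats$end,
                          strand = "+", name = sim$repeats$class),
               file.path(dir, "repeats.bed"))
  }
  ss <- Biostrings::DNAStringSet(setNames(sim$reads$seq, sim$reads$read_id))
  Biostrings::writeXStringSet(
    ss, file.path(dir, "reads.fastq"), format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(sim$reads$seq))))
  write.table(sim$truth, file.path(dir, "truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$sites_truth, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
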