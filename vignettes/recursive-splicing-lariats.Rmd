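---
title: "Detecting recursive splicing from lariat-spanning reads"
author: "rslariat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recursive splicing from lariat-spanning reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rslariat)
```

## The problem

Most introns are excised in a single pair of transesterification reactions,
leaving a branched lariat whose loop joins the intron's 5' end to the
branchpoint adenosine through a 2'–5' linkage. Some introns are instead
removed piecewise through *recursive splicing* (RS): an intronic position
carries a 3' splice site (a polypyrimidine tract and YAG) immediately
followed by a reconstituted 5' splice site (GT), so splicing to that point
regenerates a donor and the remainder of the intron is removed in a second
reaction. Each reaction still produces a lariat, and those lariats are the
most direct physical evidence of recursive splicing.

Lariat-derived cDNA is peculiar in two ways that this package exploits:

* **Inversion.** Reverse transcription around the loop produces reads in
  which the branchpoint-proximal sequence comes *before* the 5'-splice-site
  sequence — an arrangement no linear reference contains.
* **The branchpoint mismatch.** Reverse transcriptase stumbles across the
  2'–5' linkage and frequently misincorporates at the branchpoint
  nucleotide, leaving a diagnostic mismatch at a predictable position.

The pipeline therefore: scans constitutive introns for the composite motif
Y~5+~N~0–4~YAGGT; draws filtered random *decoy* positions as a negative
set; builds junction libraries (the first 20 nt of each junction as the
*head*, the last 250 nt as the *tail*); removes reads explicable by linear
alignment; maps the remainder in split fashion (exact head match, then an
end-to-end prefix alignment inside the tail whose final base is the
inferred branchpoint); and pushes the mapped junctions through a stringent
filter cascade, reporting a decoy-based empirical FDR at every stage.

## Coordinates and conventions

All coordinates are 1-based, closed intervals on the forward strand — the
GenomicRanges convention — and BED output converts at the boundary. All
motif and sequence logic operates on transcription-order sequence: minus
strand features are reverse-complemented at fetch time, while stored
coordinates stay genomic. A site's position is the first base of its
reconstituted GT; the same site acting as a 3' splice site ends one base
earlier, at the G of its YAG. The 5' splice site coordinate of an intron is
its first base (the G of GT); the 3' splice site its last base (the G of
AG).

The motif semantics are the most literal reading of the composite site:
a run of at least five *consecutive* pyrimidines whose end lies 0–4 nt
upstream of the YAG, with N matching nothing. The scanner is pinned against
two independent oracles (a per-position brute-force check and a family of
lookahead regexes) in the test suite.

## Tunable parameters

All defaults are the method's standard values and are collected in
`rs_config()`:

| parameter | default | role |
|---|---|---|
| `head_len` | 20 nt | junction head; also the minimum mapped region per side |
| `tail_len` | 250 nt | junction tail; the branchpoint must map inside it |
| `decoys_per_site` | 5 | random decoy draws per putative site |
| `decoy_window` | 250 nt | decoy exclusion range around splice-like context |
| `proximity_window` | 100 nt | same-type annotated-splice-site exclusion (inclusive) |
| `bp_dist_min`, `bp_dist_max` | 10, 60 nt | allowed branchpoint-to-3'ss distance (inclusive) |
| `mismatch_fraction` | 0.05 | minimum weighted branchpoint-mismatch read fraction |
| `selfprime_k` | 5 nt | self-primed artifact comparison length |
| `ambiguous_max_frac` | 0.05 | ambiguous-base ceiling per read (strict) |
| `mismatch_rate` | 0.0133/nt | linear-subtraction mismatch budget |
| `mc_samples` | 1000 | Monte-Carlo positions per intron |
| `bp_offset` | 25 nt | assumed median U2 branchpoint offset |
| `read_len_grid` | 75, 100, 150 nt | informative-read model grid |

Boundary conventions worth stating exactly: "fewer than 5% ambiguous
bases" is strict (a 100-nt read with five Ns is removed); "within 100 nt"
of an annotated site is inclusive (exactly 100 drops, 101 survives); the
branchpoint distance window is inclusive on both ends (10 and 60 survive,
9 and 61 do not); and the ≥5% mismatch fraction is inclusive (1 of 20
reads passes).

Two denominators differ deliberately: the *existence* rule (at least one
branchpoint-mismatch read) counts reads regardless of weight, because a
fractional weight encodes ambiguity about which 3' site produced the read,
not doubt that the read exists; the *fraction* rule uses weighted counts,
because it is a property of the junction's read population.

## The mapping contract

Linear subtraction treats a read as explained if it aligns end-to-end,
with no indels, on either strand of the transcriptome or genome with at
most `floor(0.0133 × read length)` mismatches. The built-in matcher
implements this contract exactly (an exact pass plus pigeonhole
trusted-band passes over Biostrings dictionaries), so the pipeline is
self-contained and deterministic.

Head matching is exact string search; a read matching two distinct head
sequences, or a head shared by two genes, is discarded as ambiguous. Tail
alignment permits zero mismatches, or exactly one located at the
alignment's final base — the branchpoint. Zero-mismatch lariat reads are
retained: the downstream filters *count* the mismatch fraction, which
would be meaningless if every retained read were required to carry one.
Ties within one junction's tail resolve to the most 3'-ward end (the
branchpoint closest to the 3' splice site, matching branchpoint biology);
ties across junctions are retained and shared out by `assign_weights()` as
1/k fractional weights, so each (read, 5'ss, branchpoint) observation
contributes exactly one unit of evidence.

The cascade's filters are pure predicates, so the final surviving set does
not depend on stage order (asserted as a test); the order — mismatch
existence, high confidence, proximity, repeats, branchpoint distance,
self-primed — only shapes the per-stage accounting. The empirical FDR at a
stage is `(decoy_weight / n_decoy_sites × n_putative_sites) /
putative_weight`, clipped to [0, 1]: the per-site normalisation corrects
for decoy filtering leaving fewer than five decoys per putative site, and
`NA` is reported when no putative hits remain.

In distal mode, internal cassette exons are paired with their upstream
intron's 5' splice site at *every* exonic position, with no motif
requirement; the proximity and repeat stages are replaced by the exon-body
branchpoint rule (strictly inside the exon, excluding its first and last
base), while the mismatch, high-confidence and self-primed logic still
applies by default, mirroring the scrutiny the intronic set receives.

## The informative-read model

A lariat read is *informative* only if it straddles the branchpoint with
at least 20 mappable nt on each side. For a read of length $n$ starting at
a uniform position of the loop (intron start through branchpoint, the
branchpoint assumed 25 nt upstream of the 3' splice site), the admissible
start positions number $\min(n - 40, L_\text{loop} - 20)$, clamped to
$[0, L_\text{loop}]$, giving

$$p(L_\text{loop}, n) = \frac{\min(n - 40,\; L_\text{loop} - 20)^+}{L_\text{loop}}.$$

The Monte-Carlo estimator (`informative_probability_mc()`, 1000 samples)
scores the two conditions directly; the enumeration over all loop
positions — not the closed form — is the source of truth in the tests, and
the closed form is required to match it everywhere tested. The grammatical
ambiguity in the second mapping condition is resolved as: the read must
retain at least 20 nt beyond the branchpoint to map the 5'-splice-site
head, i.e. prefix ≤ read length − 20. Beyond roughly `read_len − 40 + 25`
nt of intron length the probability decays hyperbolically, which the
package summarises by a least-squares power-law fit $y = a x^b$ on the
log–log scale (zeros excluded and counted). `weighted_length_distribution()`
turns these probabilities into the expected length distribution of
*observed* lariats under equal expression, against which mapped lariat
lengths can be compared.

## What the simulator emulates

`simulate_dataset()` generates one contig per single-transcript gene (so
every intron is constitutive by construction) with canonical GT..AG
boundaries, planted recursive-site motifs, and reads of every class the
method must tell apart: recursive and conventional lariats (inverted
order, RT mismatch with probability 0.3), linear mRNA / pre-mRNA / genomic
background, self-primed circularisation artifacts, and chimeric
template-switching artifacts. Defaults are the validation conditions: 200
genes, 50 cleanly planted sites, 100-nt reads, ten reads per planted
junction, and all artifact classes on. One seed determines every output
byte.

Choices a reader should know about:

* **Ten reads per junction.** With an RT misincorporation probability of
  0.3, ten reads give a junction a ~97% chance of showing at least one
  branchpoint mismatch, the regime the deeply sequenced total-RNA datasets
  this method targets operate in.
* **Planted branchpoints avoid the self-primed signature.** A genuine
  lariat whose branchpoint-inclusive 5-mer happens to equal the 5-mer
  upstream of its 5' splice site is, by the filter's own definition,
  indistinguishable from a self-primed artifact; planted truth avoids such
  positions, and the self-primed class is planted exactly there instead.
* **Artifacts hit decoys the way they would hit real candidates.** The
  simulator draws its decoys with the same seeded routine the pipeline
  uses, then plants artifact reads on decoy junctions in flavours that
  each violate one constraint genuine lariats satisfy: decoys within the
  proximity window of an annotated 5' splice site; decoys inside
  duplicated genomic segments (placed over decoy-eligible intron space,
  since decoys cannot land near splice-like context); branchpoint windows
  grazing a planted repeat edge; and switch points outside the 10–60 nt
  window of every reachable 3' element. A switch point *inside* some
  sibling junction's window is excluded deliberately — such a read is
  genuinely indistinguishable from a lariat of that junction.
* **Background composition** is mildly purine-biased (A/G 0.28, C/T 0.22)
  to keep the spurious motif density low but non-zero, so discovery tables
  always contain unplanted candidates.
* **Constant base qualities** are emitted; the pipeline ignores quality.

What the simulator does *not* emulate — and what passing its tests
therefore cannot show about real data: expression-level variation between
genes (lariat recovery in real libraries is strongly expression-driven),
paired-end reads, indels and structured sequencing error, incomplete or
conflicting
annotation, alternative splicing beyond the cassette-exon flag, and the
full repeat landscape of a mammalian genome. Simulated sizes are also
small: validation runs use ~200 genes and a few thousand reads so the
whole suite executes in minutes on one core; the algorithms are linear in
reads × candidate junctions and carry no genome-scale assumptions.

## Known limitations

* Reads are mapped in transcription orientation only; an antisense
  sequencing protocol would need reads reverse-complemented upstream.
* The self-primed filter keeps (with a warning) reads whose 5' splice site
  sits within 5 nt of a contig edge, where the comparison 5-mer does not
  exist.
* Uniqueness checks count exact 20-mer occurrences on both strands; a
  self-reverse-complementary 20-mer would be counted twice and thus
  conservatively rejected.
* Decoys are not redrawn after filtering, matching the described decoy
  bookkeeping; decoy counts per intron are therefore variable.
* A single annotation file is taken as the truth for both constitutive
  introns and the transcriptome used in subtraction; merging multiple
  annotation sources is out of scope.

## A minimal run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$genome, sim$exons, sim$reads,
                    repeats = sim$repeats,
                    config = rs_config(seed = cfg$seed))
res$cascade            # per-stage survivors and empirical FDR
res$cascade$sites      # final recursive-site table
```
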