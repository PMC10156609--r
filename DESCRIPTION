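Package: rslariat
Title: Recursive Splicing Discovery from Lariat-Spanning RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recursive splice sites in constitutive introns from total
    RNA sequencing by split-read mapping of intron lariats. Scans introns for
    the composite 3'/5' splice-site motif (polypyrimidine tract, YAG, and a
    reconstituted GT), generates filtered random decoy sites for empirical
    false-discovery-rate estimation, builds junction head/tail libraries,
    maps inverted lariat-spanning reads with branchpoint inference from the
    reverse-transcriptase mismatch signature, and applies a stringent filter
    cascade. Includes an informative-read probability model with a power-law
    fit over intron length, a distal-exonic mode for cassette exons, and a
    seeded read simulator producing genome, annotation, reads, and truth
    labels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
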