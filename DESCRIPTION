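Package: riddseq
Title: Discovery of IRE1-Dependent Decay (RIDD) Targets from Exon-Level RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate substrates of the IRE1 endoribonuclease from
    poly(A)-selected RNA-seq of in vitro cleavage assays. Cleaved transcripts lose
    their 5' fragment during poly(A) selection, so RIDD (regulated IRE1-dependent
    decay) targets show depleted read counts in exons 5' of the cleavage site.
    The package simulates such experiments with planted XBP1-like hairpins,
    flattens gene models into disjoint exon bins, tests each bin for differential
    exon usage with a negative-binomial likelihood-ratio test, localizes the
    cleavage region as a two-segment change-point of the usage profile, scans the
    region for the CUGCAG consensus inside a stem-loop, and implements the
    downstream validation arithmetic: 2^-deltaCt qPCR quantification, ER-stress
    decay calls with IRE1-inhibitor rescue, protein half-life estimation, and
    Chou-Talalay median-effect/combination-index synergy analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
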