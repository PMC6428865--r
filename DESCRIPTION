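Package: riboTE
Title: Differential Translation Efficiency Testing and Translational
    Class Profiling for Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes whose translational efficiency changes
    between two conditions from paired mRNA-seq and ribosome-protected
    fragment (RPF) count tables, using a negative-binomial generalized
    linear model with an assay-by-condition interaction term tested by a
    Wald test, with median-of-ratios normalization and moderated
    method-of-moments dispersion estimation. Significant genes are
    classified into behavioral subgroups (translationally activated or
    repressed, with buffered, decreased or increased mRNA levels) and
    characterized by codon-level RPF metagene profiles, structure-score
    (PARS) profiles anchored at the translation initiation site, gene
    architecture comparisons, and genomic run-on derived synthesis-rate
    and half-life calculus. A synthetic-data generator with known ground
    truth makes every stage testable end to end, and a pipeline driver
    orchestrates simulate/analyze/report runs reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
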