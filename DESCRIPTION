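Package: acariscan
Title: Acaricide Resistance Monitoring by Probit Bioassay Analysis and
    Quantitative Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for two-spotted spider mite (Tetranychus urticae)
    acaricide-resistance monitoring. Fits probit dose-mortality models to
    residual contact vial (RCV) bioassay data, estimates LD50/LD90 with
    confidence intervals and goodness-of-fit, and derives discriminating
    diagnostic doses (2 x LD90). Calibrates quantitative sequencing (QS)
    regressions that convert Sanger chromatogram peak-height ratios at
    target-site resistance SNPs into pooled resistance-allele frequencies
    with 95% detection limits, and quantifies phenotype-genotype
    relationships by Spearman rank correlation with heat-map reporting.
    Ships the published T. urticae target-site mutation panel (AChE, VSSC,
    GluCl, CHS1, cytochrome b) and a synthetic-data generator for
    bioassays, chromatogram peak signals and linked strain panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    pheatmap,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
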