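Package: metcall
Title: MET Exon-14 Skipping and mRNA Over-Expression Calling from
    Targeted Probe Counts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls MET exon-14 skipping (METdelta-ex14) and tiers MET mRNA
    over-expression in non-small-cell lung cancer cohorts from nCounter-style
    digital probe counts. Implements housekeeping-geomean sample QC, two-step
    positive-control and housekeeping normalization, cohort-adaptive
    mean + k*SD cutoffs on the delta-ex14/wild-type log-ratio and on log-MET
    expression, distribution diagnostics (Lilliefors normality, two-component
    Gaussian mixture bimodality), rank-based group comparisons, and the
    cross-method concordance statistics (percent agreement with Wilson
    intervals, Cohen's kappa, sensitivity/specificity) used to validate such
    assays. Includes a negative-binomial cohort simulator with ground-truth
    labels and in-silico cell-line spike-in mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
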