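Package: targetDeconv
Title: Targeted Cell-Type Deconvolution from Methylation Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates cell-type proportions of bulk samples from a small
    panel of cell-type-specific CpG methylation markers assayed by targeted
    bisulfite amplicon sequencing. Provides priority-score marker selection
    from sorted-cell fragment-coverage matrices, methylation calling with
    blank-based background filtering and duplicate merging, reference-panel
    construction from sorted cells, proportion estimation by ordinary least
    squares and by an iterative weighted non-negative least-squares
    estimator that down-weights CpGs with high cross-subject variance,
    evaluation against known mixtures (correlation, bias, precision, RMSE)
    and leave-one-amplicon-out robustness analysis, plus a synthetic-data
    generator for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
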