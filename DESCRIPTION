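Package: ewasthresh
Title: Significance Thresholds for Epigenome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates multiple-testing significance thresholds for
    epigenome-wide association studies (EWAS) on CpG methylation arrays.
    Implements a label-permutation minimum-P (maxT) null with per-CpG
    two-sample t-tests, effective-number-of-independent-tests estimation by
    Bonferroni inversion and beta-distribution modelling of the minimum-P
    distribution, simulation extrapolation of the threshold to saturated
    genome-wide CpG density via subsampling and a Monod (saturating growth)
    fit, and non-central-t power machinery to re-derive EWAS sample-size
    requirements under the estimated thresholds. Ships a synthetic
    450k-like methylation data generator with distance-decaying
    co-methylation so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
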