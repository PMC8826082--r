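Package: nichespan
Title: Niche Breadth Quantification for Experimental Evolution Across a
    Chemical Environmental Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how laboratory evolution changes the
    breadth of adaptation of bacterial strains across a gradient of medium
    compositions. Converts plate-reader OD600 time series into maximal
    growth rates via the best five-interval window rule, fits cubic
    polynomial fitness profiles along log-scaled concentration gradients of
    individual medium constituents, and summarises them into the normalized
    niche-space statistic S and the niche broadness total S_T. Includes a
    simulator of the serial-transfer evolution protocol with stepwise
    mutation fixation, a synthetic-data generator with known ground truth
    for end-to-end testing, and the statistical comparisons
    (exact-permutation Spearman correlation, per-condition Welch t tests)
    used to summarise the results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
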