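Package: nanoclustr
Title: Nanocluster Quantification for Super-Resolution Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of receptor nanoclusters from
    single-molecule localization microscopy (SMLM) and STED-style images.
    Implements Ripley's K and Getis-Franklin local point-pattern statistics
    with Monte-Carlo envelopes under complete spatial randomness,
    density-matched threshold calibration and interpolated cluster maps,
    Costes auto-threshold Pearson co-localization, a cluster-association
    statistic with a spatial-randomization null conditioned on cluster-size
    tertiles, nonparametric group comparisons with Dunn's post-tests, and
    synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    EBImage,
    spatstat.explore,
    spatstat.geom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
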