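Package: benchdrift
Title: Modeling, Prediction and Correction of Pre-Centrifugation Drift in
    Plasma Metabolomics Feature Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for handling pre-analytical variability in plasma NMR
    metabolomics feature tables. Blood samples that sit before centrifugation
    undergo reproducible, temperature-dependent changes ("drift") in many
    metabolite features. benchdrift normalizes feature tables by the
    probabilistic quotient method, clusters features that share a drift
    profile, fits an anchored cubic-spline drift function per cluster, and
    corrects intensities back to a 1 h reference state using either recorded
    or model-predicted pre-centrifugation times. Pre-centrifugation
    temperature and delay time are predicted by random-forest models with
    recursive variable selection inside a repeated double cross-validation
    scheme, with permutation-based significance. A synthetic study generator
    with full ground truth supports validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
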