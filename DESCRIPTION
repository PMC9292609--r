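Package: tgpgerm
Title: Thermal Germination Niche Modelling from Thermogradient-Plate Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse seed germination experiments run on bidirectional
    thermogradient plates (TGPs). Provides half-grid plate designs,
    ingestion and viability adjustment of cumulative germination scoring
    data, regularization of irregular scoring intervals, a registry of
    germination indices (final proportion, t50, mean germination time,
    synchrony, uncertainty and more), binomial generalized additive
    models of germination over day and night temperature with automated
    candidate comparison by Monte Carlo holdout resampling, and monthly
    germination predictions under current and future climates at any
    coordinate. Includes a synthetic-experiment generator with known
    ground truth for validation, quilt-plot visualization, and a
    scripted end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
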