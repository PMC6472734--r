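Package: fcharmony
Title: Traveling-Subject Harmonization and Site-Bias Decomposition for
    Multisite Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes site differences in multisite resting-state
    functional-connectivity data into engineering measurement bias and
    biological sampling bias by jointly fitting a constrained, L2-regularized
    per-edge regression to a multisite patient dataset and a traveling-subject
    dataset. Provides traveling-subject harmonization alongside GLM, adjusted
    GLM, and parametric empirical-Bayes ComBat harmonizers; generative models
    for sampling-bias variance as a function of site sample size with
    AICc/BIC comparison and leave-one-site-out prediction; factor summaries
    (magnitude moments, contribution sizes, dispersion tests, bias-disorder
    correlations, ROI projection, hierarchical clustering, per-edge site
    ANOVA); a twofold cross-validation evaluation of harmonization
    performance; a preprocessing pipeline from ROI time series to Fisher-z
    connectivity (scrubbing, 36-parameter nuisance regression, band-pass
    filtering); and a synthetic-data generator emulating the multisite plus
    traveling-subject study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
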