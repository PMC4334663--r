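Package: megmyelin
Title: Linking MEG Dipole Moments to Quantitative MRI Myelin Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for relating auditory evoked-field source
    strength to cortical myeloarchitecture. Provides an analytic spherical
    forward model for MEG current dipoles, variational-Bayes two-dipole
    fitting with free-energy model evidence, quantitative-map handling
    (R2* estimation, smoothing, tissue masks, grey-matter-masked ROI
    averaging), a summed Spearman-correlation permutation test across maps
    and regions of interest, Bayesian general linear models with
    model-evidence and family-level comparison, and a synthetic-data
    generator that emulates the study conditions end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
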