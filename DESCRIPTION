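Package: hepafat
Title: Liver Proton-Density Fat Fraction from Gradient-Echo MRI and PRESS MRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hepatic steatosis as the proton-density fat fraction
    (PDFF) from magnitude gradient-echo image series (triple- and multi-echo,
    with a multipeak fat spectral model, T2* correction and Rician noise-bias
    correction) and from multi-TE single-voxel PRESS spectra (time-domain peak
    fitting, per-peak T2 correction and hidden-peak restoration). Includes a
    synthetic phantom and cohort generator calibrated to a diabetic NAFLD
    population, NASH-CRN histology grading, and the diagnostic-accuracy layer:
    Spearman correlation, empirical and smoothed ROC curves with Youden
    thresholds, DeLong paired AUC comparison, the Obuchowski ordinal AUC, and
    linear models of histology steatosis on PDFF with steatohepatitis and
    fibrosis covariates.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
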