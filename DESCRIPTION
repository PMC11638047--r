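Package: dcequant
Title: Quantitative DCE-MRI Pharmacokinetic Analysis for Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative dynamic contrast-enhanced (DCE) MRI
    analysis of tumor therapy response. Implements B1-corrected variable
    flip angle R1 mapping, Tofts-model and shutter-speed-model (two-site
    water exchange) pharmacokinetic fitting at voxel and ROI level with
    fixed or measured native R1, model-based bolus arrival time alignment,
    signal enhancement ratio maps, cellular water efflux (k_io) filtering
    with EES concentration sensitivity maps, per-tumor histogram summaries,
    and cohort-level response statistics (visit percent changes, Wilcoxon
    rank-sum comparison, logistic-regression ROC with DeLong confidence
    intervals). A digital-reference-object cohort generator produces
    synthetic patients (DCE series, VFA series, B1 maps, ROI masks, ground
    truth) with configurable longitudinal group effects so every pipeline
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pROC,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
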