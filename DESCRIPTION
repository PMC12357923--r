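Package: adipotrace
Title: Nuclear-Translocation Scoring, Glucose-Flux Arithmetic and
    Compound-Identity Calculations for Metabolic Phenotyping Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative procedures used in diet-induced-obesity studies of
    glucoregulatory plant extracts: per-cell nuclear-translocation scoring
    from two-channel fluorescence micrographs (nuclei segmentation with size
    and circularity filters, perinuclear-ring intensity ratios),
    hyperinsulinemic-euglycemic clamp and radiotracer glucose-flux
    calculations (steady-state glucose infusion rate, turnover, endogenous
    glucose production, tissue 2-deoxyglucose uptake), extracellular
    acidification metrics, baseline-referenced area-of-curve for tolerance
    tests, high-resolution mass-spectrometry adduct m/z and ppm-error
    arithmetic with external-standard quantification, body-surface-area dose
    translation, Grubbs outlier screening and delta-delta-Ct expression.
    Ground-truth-labelled synthetic generators (plate images, clamp traces,
    tracer curves) make every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
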