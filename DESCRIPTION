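Package: hetpet
Title: Texture Heterogeneity of PET Lesions for Radioligand Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumoral textural heterogeneity of PET lesions
    and screens it against post- versus pre-therapy changes in clinical
    markers. Computes five heterogeneity parameters per volume of interest
    (coefficient of variation, and gray-level co-occurrence entropy,
    homogeneity and contrast, plus a neighborhood gray-tone size-variation
    statistic) together with mean standardized uptake value, aggregates
    lesions to patient level by metastatic site, derives responder labels
    from marker declines, and evaluates candidate predictors with Spearman
    screening, nonparametric ROC analysis (Hanley-McNeil standard errors),
    Youden-index cutoffs and AND-rule test combination. A seeded synthetic
    phantom cohort generator (ellipsoidal lesions carrying Gaussian
    random-field textures linked to outcome through a Gaussian copula)
    makes the whole pipeline testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
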