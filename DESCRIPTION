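Package: xerograd
Title: Dose-Gradient and Parotid-Migration Models of Radiation-Induced
    Xerostomia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Normal tissue complication probability (NTCP) modelling of
    moderate-to-severe (CTCAE grade >= 2) xerostomia after head-and-neck
    radiotherapy from planned-dose features and anatomical change.
    Extracts the parotid gland mean dose (MD) and the average lateral
    dose gradient (GRADX) from volumetric dose grids and structure
    masks, estimates inter-fraction parotid gland migration (PGM) from
    serial external-contour volumes at the C2 vertebra level, pools
    CTCAE follow-up reports into a binary endpoint, and fits nested
    logistic models evaluated by leave-pair-out cross-validated AUC with
    bias-corrected and accelerated (BCa) bootstrap confidence intervals,
    partial dependence profiles, and median-split stratification.
    Includes an analytic phantom and cohort simulator so the full
    pipeline can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
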