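Package: eusquant
Title: Quantitative Gray-Level Analysis of Endoscopic Ultrasound Images of
    Pancreatic Cystic Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrated first-order gray-level analysis of B-mode endoscopic
    ultrasound still frames of pancreatic cystic lesions. Turns per-image
    annotations (free-hand lesion polygon, tolerance-based cystic seed points,
    reference parenchyma circles) into pixel masks by polygon rasterization and
    seeded region growing, and computes echogenicity (mean gray value),
    inhomogeneity (gray-value standard deviation), integrated density per
    calibrated area, part areas, cystic/whole area ratio and cystic lobule
    counts for the whole lesion and its cystic and solid parts. Includes the
    cohort statistics stage (normality battery, routed parametric or
    non-parametric two-sample comparisons, chi-squared tests), a seeded
    ground-truthed synthetic phantom generator for validation, and a
    command-line pipeline over cohort manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    jpeg,
    png,
    stats,
    utils
Suggests:
    optparse,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
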