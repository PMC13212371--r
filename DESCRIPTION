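Package: iacdens
Title: Density Quantification and Determinant Modelling of Intracranial
    Arterial Calcification on Non-Contrast CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-level quantification of arterial calcification on
    non-contrast CT: volume and mean density above a 130-HU detection
    floor, re-measured across a ladder of Hounsfield-unit thresholds
    (200-1000 HU), with maximum-density categorization into seven ordinal
    bins and aggregation to the intracranial carotid (ICAC),
    vertebrobasilar (VBAC) and overall (IAC) arterial beds.  Includes
    Kockelkoren-score subtype classification (intimal / ambiguous /
    medial) with density-by-subtype comparisons, a synthetic CT phantom
    generator with exact ground truth for validating the measurement
    core, a cohort simulator (covariate marginals, proportional-odds
    ordinal outcomes, copula-linked density-volume pairs), and the
    inference chain: Spearman correlation with bootstrap confidence
    intervals, a self-contained Newton-Raphson proportional-odds fitter
    reporting common odds ratios, and linear models on standardized
    log-transformed outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
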