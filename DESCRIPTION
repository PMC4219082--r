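Package: ctces
Title: Automated Brain CT Densitometry and Cerebral Edema Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated densitometry of unenhanced axial brain computed
    tomography (CT). Implements a six-stage artifact-elimination algorithm
    that isolates intracranial pixels (cranium detection, gantry removal,
    quadrant coordination, fracture and craniotomy sealing via pseudo-cranial
    pixels, convex-tissue elimination, and Hounsfield-Unit bounding),
    computes per-image and per-series Hounsfield-Unit density distributions,
    derives the Cerebral Edema Score (proportion of intracranial pixels with
    HU 17-24) and its mortality variant (HU 19-23), and provides the
    cohort-level statistical machinery: per-bin nonparametric scans,
    discriminative-band discovery, ROC cutoff selection and categorical
    tests. A seeded synthetic head-phantom generator with ground-truth masks
    supports end-to-end validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
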