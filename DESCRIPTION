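Package: neuroreserve
Title: Neural Perimetry, Mismatch Classification and Training-Effect
    Inference for Homonymous Visual Field Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidy pipeline linking fMRI-based neural perimetry to
    training-induced visual field recovery in hemianopia. Implements
    rotating-wedge and expanding-ring stimulus apertures, forward
    modelling and grid-plus-refinement fitting of circularly symmetric
    Gaussian population receptive fields (pRFs), visual-field coverage
    maps downsampled to the Humphrey SITA 30-2 perimetric grid, the
    four-category Humphrey/retinotopy mismatch classification,
    per-category training-effect estimation with a within-patient
    permutation null, goal-attainment association, and a synthetic-cohort
    generator emulating lesioned retinotopic cortex with spared islands,
    hill-of-vision sensitivity maps with scotomas, and
    category-dependent training effects.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
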