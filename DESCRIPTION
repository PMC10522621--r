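Package: deepdiet
Title: Stomach-Content Diet Analysis and Foraging-Depth Estimation for
    Deep-Sea Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative stomach-content analysis of midtrophic
    pelagic fishes sampled as prey of larger predators. Implements diet
    composition indices (mean proportional abundance and mass, frequency
    of occurrence, prey-specific proportional mass, index of relative
    importance), family-level rollups with mutually exclusive prey
    categories, Morisita-Horn similarity with ANOSIM, PERMANOVA, PERMDISP
    and non-metric multidimensional scaling, coverage-based Hill-Shannon
    diversity estimation over prey families, prey-size imputation from
    partially measured prey groups with family-level length-mass models,
    log-scale allometric models of prey size and number, and a
    mass-weighted foraging-depth estimator that maps stomach contents onto
    the vertical habitat of the prey. A synthetic stomach-content
    generator with known ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS
Config/testthat/edition: 3
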