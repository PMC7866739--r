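Package: grnnfoa
Title: General Regression Neural Network Modeling with Fruit-Fly Optimization
    for Elicited Plant Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits general regression neural networks (Gaussian kernel
    regression) to designed elicitation experiments in plant cell suspension
    culture, with the smoothing parameter tuned by a fruit-fly optimization
    algorithm under repeated k-fold cross-validation. Quantifies input
    importance by leave-one-covariate-out sensitivity ratios (VSE/VSR) and
    maximizes predicted growth and paclitaxel yield over the culture-input box
    with fruit-fly and genetic-algorithm optimizers. Includes a synthetic-data
    generator emulating a factorial fungal-elicitor experiment (cell extract
    and culture filtrate dose, elicitor adding day, harvest time), Box-Cox
    response normalization, PCA outlier screening, and a command-line
    interface binding the stages into a reproducible workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
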