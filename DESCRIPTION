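Package: chromadiet
Title: Chromatic Scene Statistics and Colour Psychophysics of the Visual Diet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterizing the chromatic statistics of visual
    environments ("visual diets") sampled with calibrated RGB cameras, and for
    relating those statistics to colour perception. Converts camera RGB to
    cone excitations and MacLeod-Boynton chromaticities, filters and
    subsamples RAW-style images, fits standard-deviation ellipses and
    blue-yellow log axis ratios to per-image chromaticity distributions, and
    computes mean saturations in opponent hue wedges. Simulates and analyses
    four-alternative forced-choice colour discrimination experiments
    (multiplicative adaptive staircases, maximum-likelihood logistic
    psychometric fits with a 45 percent-correct threshold criterion,
    discrimination-ellipse fits, colour-vision-deficiency screening),
    generates axis-constrained chromatic Mondrian stimuli, and analyses
    colour-preference rankings against environment statistics (permutation
    null bands, Spearman correlations, Zou confidence intervals for dependent
    correlation differences). Includes synthetic-data generators so the whole
    pipeline can be exercised end-to-end without access to the original
    privacy-restricted imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
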