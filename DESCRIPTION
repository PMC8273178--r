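Package: chromsupp
Title: Chromatic Suppression of Luminance Responses: Stimuli, HRF Fitting
    and Psychometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline for a vision-neuroscience paradigm in
    which weakly saturated colored patches suppress luminance-driven cortical
    responses. Generates the visual stimuli of both experiments (Munsell-chip
    patch patterns on textured or black backgrounds, scrambled controls,
    exponentially enveloped gratings and mask textures); models block-design
    BOLD responses with a two-Gaussian-pulse hemodynamic response function
    fitted jointly across chroma conditions under shared temporal parameters;
    fits cumulative-Gaussian psychometric functions to two-alternative
    forced-choice contrast-discrimination data; and runs the group statistics
    (one-way repeated-measures ANOVA, Tukey HSD, t comparisons). Seeded
    synthetic-data generators emulate the block schedules, BOLD time courses
    and Bernoulli 2AFC observers the analysis assumes, so the whole chain runs
    end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    munsell,
    ggplot2,
    withr
Config/testthat/edition: 3
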