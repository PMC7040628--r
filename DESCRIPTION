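Package: xylokin
Title: Xylogenesis Kinetics from Microcore Cell Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing intra-annual wood formation (xylogenesis)
    monitored by repeated microcore sampling. Smooths seasonal counts of
    cambial, enlarging, wall-thickening and mature tracheids with penalized
    regression splines and a per-tree random intercept, inverts the smoothed
    curves into per-cell differentiation kinetics (entrance dates, residence
    durations in enlargement and wall deposition, enlargement and wall
    deposition rates), standardizes tracheidograms to relative in-ring
    position, derives cambial phenology metrics including uni/bimodal
    classification, and compares treatment groups via pointwise
    confidence-band overlap, one-way ANOVA with Tukey HSD, and linear mixed
    models. Includes a seeded forward simulator of a wood-formation season
    for ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
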