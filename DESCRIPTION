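Package: plsface
Title: Two-Block Partial Least Squares for Facial Action-Unit Trial Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns frame-level facial action-unit (AU) tracking output in
    OpenFace-style CSV files into per-trial behavioural covariates (the range
    of each AU's expression and the proportion of time the gaze is fixed on
    the screen), assembles them together with binary experimental-design
    indicators into two aligned blocks, and decomposes their joint structure
    with a two-block partial least squares (2B-PLS) model fitted by singular
    value decomposition of the between-block covariance. Reports latent
    structures, variance shares (scree), correlation loadings with a t-test or
    permutation significance mask, and plot-ready tables. Includes a
    synthetic-cohort generator with planted gender, stimulus-type, trial-order
    and subject effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
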