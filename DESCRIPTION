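Package: zlda
Title: Z-Score Linear Discriminant Analysis for Heteroscedastic Binary
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary linear discriminant classification for heteroscedastic
    class distributions, as met in EEG-based brain-computer interfaces.
    Fits the least-squares linear discriminant, summarises the projected
    weight sums of each class by a Gaussian (mean and standard deviation),
    and classifies new samples by comparing per-class z-scores, which
    shifts the decision boundary toward the class with the smaller
    projected spread.  Includes a Monte-Carlo simulation harness comparing
    the z-score rule against the conventional midpoint rule on
    two-dimensional Gaussian classes, and a common-spatial-patterns (CSP)
    front-end (artifact rejection, zero-phase band-pass filtering, spatial
    filtering, log-variance features) so the full motor-imagery pipeline
    runs on synthetic multichannel trials.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
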