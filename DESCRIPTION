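Package: lapnb
Title: Laplacianised Naive Bayes for Binary Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bernoulli naive Bayes classification of compounds described by
    binary fingerprints, with Beta-prior conjugate ("Laplacian corrected")
    smoothing of the class-conditional feature probabilities. Implements the
    full posterior discriminant that scores both present and absent features,
    the widely used present-features-only shortcut (the Laplacian Corrected
    Modified Naive Bayes, LCMNB, of Xia and co-workers) as a special case of
    the Beta-smoothed posterior, and diagnostics that quantify, on any
    dataset, whether discarding the absent-feature contributions is
    justified. Includes a class-conditional Bernoulli fingerprint simulator,
    dense and sparse fingerprint file formats, lossless model serialization,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
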