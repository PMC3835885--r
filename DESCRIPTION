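Package: cstfp
Title: Common Spatio-Time-Frequency Patterns for Two-Class Multichannel Signal Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint data-driven design of spatial weights, FIR bandpass filters,
    and binary time windows that maximize a common-spatial-patterns style
    discriminative variance ratio between two classes of equal-length
    multichannel trials (e.g. motor-imagery EEG epochs). Filters are designed
    sequentially with a deflation constraint enforcing spectral diversity, and
    each triple is optimized by alternating generalized-eigenvalue updates for
    the spatial weights and filter coefficients with an exhaustive search over
    a finite candidate set of binary time windows. Includes log-variance
    feature extraction with per-filter CSP banks, a Fisher discriminant
    classifier with midpoint threshold, a stratified repeated cross-validation
    harness, a synthetic-trial generator with known narrowband sources for
    validation, and text-based trial and model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    signal,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
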