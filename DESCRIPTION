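Package: symbolichar
Title: Symbolic Representation and Classification of Inertial Sensor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discretizes triaxial accelerometer time series into symbolic words
    with SAX (piecewise aggregate approximation over equal-probability Gaussian
    breakpoints) and SFA (Fourier-coefficient quantization via multiple
    coefficient binning, with a supervised ANOVA/information-gain variant), and
    classifies activities from bags of words with SAX-VSM, BOSS 1-NN, BOSS-VS
    and WEASEL. Includes three strategies for fusing the x, y and z axes into
    one-dimensional symbolic pipelines (axis stacking, signal magnitude, first
    principal component), time- and frequency-domain baseline features, a
    synthetic activity-signal generator, and a cross-validation harness that
    also accounts for representation size and stage timings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    glmnet,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
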