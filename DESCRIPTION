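Package: arnn
Title: Auto-Reservoir Computing for Multistep-Ahead Prediction from
    Short High-Dimensional Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multistep-ahead forecasting of a target variable from a
    short-term, high-dimensional multivariate time series via
    spatiotemporal information (STI) transformation.  A fixed, randomly
    weighted multilayer tanh network (an auto-reservoir driven by the
    observed system itself rather than by external dynamics) maps each
    high-dimensional snapshot to a feature vector; primary and conjugate
    linear readouts between those features and the delay-coordinate
    (Hankel) representation of the target are then fitted jointly with
    the unknown future values by alternating ridge least squares with a
    dropout scheme.  Includes the linearized-STI baseline solver, plug-in
    mutual-information variable selection, a coupled-Lorenz benchmark
    simulator (time-invariant, noisy and time-varying regimes) and
    normalized-RMSE/PCC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
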