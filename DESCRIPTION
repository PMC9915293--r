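Package: alpcodec
Title: Lossless ECG Compression by Adaptive Linear Prediction and
    Golomb-Rice Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lossless compression of integer-quantized electrocardiogram
    (ECG) signals. Each sample is predicted by four fixed
    binomial-coefficient linear predictors (orders 1-4); the predictor with
    the smallest absolute residual is selected per sample and the signed
    residual is entropy-coded with a Golomb-Rice code whose divisor
    exponent adapts causally to the mean absolute residual of the three
    most recent samples. Includes an exact decoder and bit-exact binary
    container, a linear-prediction coefficient estimation toolkit
    (autocorrelation, Yule-Walker, Levinson-Durbin), a seedable synthetic
    ECG generator emulating common acquisition setups (MITDB-, EDB- and
    PTBDB-like), readers for WFDB digital records and integer CSV streams,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
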