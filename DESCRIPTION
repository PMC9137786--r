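Package: cgmcast
Title: Glucose Forecasting for Virtual Pediatric Type 1 Diabetes Patients
    with Edge Quantization Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual pediatric type 1 diabetes patients with a
    minimal-model glucose-insulin core under randomized meal schedules and
    perturbed insulin boluses, engineers insulin-on-board features, trains
    convolutional and LSTM neural networks for 30-minute-ahead continuous
    glucose monitoring forecasts, emulates 8-bit post-training quantization
    (dynamic-range and full-integer) including uint8 overflow reconstruction,
    and evaluates predictions with RMSE and Clarke Error Grid analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
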