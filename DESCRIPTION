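Package: lwplsri
Title: Online Interpolation of Missing R-R Intervals by Locally Weighted
    Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects missed R-wave events in a streaming R-R interval (RRI)
    tachogram and reconstructs the two underlying beats from a local
    partial-least-squares model fitted just-in-time on a FIFO buffer of
    recent beats. Includes the eigenvalue-NIPALS PLS and locally weighted
    PLS (LWPLS) regression engines, baseline interpolators (buffer mean,
    equal division), time- and frequency-domain heart-rate-variability
    feature extraction over a sliding window (Burg autoregressive spectra
    of the 4 Hz resampled tachogram), a seeded generator of realistic
    sinus-rhythm RRI series, and a simulation harness that benchmarks the
    interpolators on artificially degraded tachograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
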