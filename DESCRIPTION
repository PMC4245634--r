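Package: anomalag
Title: Weekly Temperature Anomalies and Distributed Lag Nonlinear Count Models
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying short-term associations between daily
    temperature and daily event counts (such as suicide deaths).  Computes
    day-of-year climatologies and daily anomalies, trailing seven-day
    aggregates, percentile-based classification of high-end and low-end
    count weeks, temperature-anomaly categories and their contingency
    tables, and a from-scratch distributed lag nonlinear model (natural
    cubic spline exposure basis crossed with a lag polynomial basis,
    Poisson log-link regression fitted by iteratively reweighted least
    squares) with cumulative relative-risk prediction against the median
    exposure and an AIC sensitivity grid.  Includes a calibrated synthetic
    daily-series generator with a known, recoverable temperature effect for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
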