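Package: netdyn
Title: Functional Connectivity and Dynamics of Resting-State Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links the functional connectivity of resting-state brain
    networks (within-network cohesion, between-network integration) to
    their dynamic properties (synchrony and metastability of the Kuramoto
    order parameter). Provides maximal-overlap discrete wavelet band-pass
    filtering and Hilbert analytic-signal phase extraction for regional
    BOLD time series, per-network order-parameter metrics, a delay-coupled
    Kuramoto simulator constrained by structural connectomes (tract
    lengths converted to conduction delays), coupling-strength sweeps with
    empirical-vs-simulated model fitting, bootstrap statistics, and a
    synthetic-data generator with known ground-truth synchrony for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    car,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
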