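Package: gpsrhythms
Title: Digital Phenotyping of Mobility Rhythms from Smartphone GPS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates duty-cycled smartphone GPS trajectories and daily
    ecological momentary assessment (EMA) mood series for a three-group
    cohort (healthy controls, bipolar disorder, major depressive disorder),
    preprocesses raw fixes into stationary/moving state segments, computes
    eight daily mobility features (location variance, speed mean and
    variance, number of clusters, entropy, homestay, transition time, total
    distance), transforms feature series into Fourier power spectra with a
    top-5 peak ranking and group consensus procedure, and fits the
    group-comparison and person-day logistic models that link mobility to
    mood state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
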