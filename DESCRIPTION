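Package: arsHMM
Title: Multi-Scale Area-Restricted Search from Animal Telemetry with Hidden
    Markov Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterises nested (broad and focussed)
    area-restricted search in central-place foraging marine predators from
    regularised GPS telemetry. Implements multivariate discrete-time hidden
    Markov models with a-priori known behavioural states (non-diving,
    unknown), gamma step-length and wrapped-Cauchy turn-angle state-dependent
    distributions, maximum-likelihood fitting with random restarts, Viterbi
    decoding, forward-backward state probabilities, pseudo-residuals and
    BIC-based order selection. Downstream, nested binomial "use-encounter"
    habitat-association models are fitted as penalised-spline logistic
    regressions with individual random intercepts, with posterior-draw
    prediction and state-uncertainty sensitivity analysis. A synthetic-data
    generator (tracks, dive summaries, haulout events, gridded seascapes)
    makes the full pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
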