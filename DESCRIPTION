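Package: fatiguedyn
Title: Trial-by-Trial Dynamics of Subjective Fatigue and Effort Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits dynamic latent-state models of subjective fatigue to
    trial-by-trial ratings collected during repeated grip-force exertion.
    Fatigue is decomposed into a recoverable component that rises with
    exertion and falls with rest, and an unrecoverable component that only
    accumulates, on top of a per-person baseline. Perceived-effort ratings
    are modelled as fatigue-weighted exertion. The package provides
    per-participant least-squares fitting over a factorial grid of
    Nelder-Mead starts, AIC-based model comparison with random-effects
    Bayesian model selection (exceedance probabilities), force-trace
    processing (area under the curve, success judging), a counterbalanced
    task-sequence generator, and a synthetic-cohort simulator for parameter
    and model recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
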