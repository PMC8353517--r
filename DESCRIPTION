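Package: ghostr
Title: Defensive Ghosting and Pass-Completion Modelling for American Football Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates league-average defensive movement ("ghosting") in American
    football pass plays from player tracking data in the NFL Big Data Bowl 2021
    CSV dialect. Provides reading, filtering and normalisation of snap-to-pass
    tracking windows; unsupervised tactical role alignment via Gaussian mixture
    models, a Gaussian-emission hidden Markov model and Hungarian matching;
    per-role recurrent (LSTM) movement policies trained by multi-agent imitation
    learning with dataset aggregation (DAgger) and alternating role/policy
    optimisation; an order-invariant formation-based pass-completion probability
    model (neural network and gradient-boosted trees); rollout-error and
    completion-probability evaluation of ghosted against observed defenses; and a
    synthetic play generator with scripted man/zone coverage and a known
    completion-probability ground truth for end-to-end testing without the NFL
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    splines,
    stats,
    utils,
    xgboost
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
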