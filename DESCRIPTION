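Package: stridenet
Title: Within-Stride Metabolic Cost Estimation from Stride-Average Values
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates within-stride (per-gait-phase) metabolic cost time
    series from a single stride-average value using three small trainable
    networks: an untied autoencoder whose scalar latent is pinned to the
    stride mean, a tied-weight autoencoder whose decoder weights are live
    transposes of the encoder weights, and a direct scalar-to-series
    expander. Includes a seeded synthetic gait dataset generator emulating
    perturbed-walking simulation experiments, full-batch Adam training with
    the mean-pinned reconstruction loss, a hyperparameter sweep harness
    (layer count, middle-layer activation, epoch count, aggregated over
    repeated trainings), Pearson-correlation validation against the
    significance threshold for n = 100 phase samples, and mean-to-series
    surface profiling of trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Regression, TimeCourse, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
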