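Package: avstates
Title: Neuronal Avalanche Brain-State Dynamics from Region-Level Neural Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts neuronal-avalanche patterns from region-by-time neural
    recordings (z-scoring, 3-SD binarization, avalanche detection and pattern
    vectorization), embeds the unique patterns with a diffusion-based
    dimensionality reduction (adaptive alpha-decay kNN kernel, Markov
    normalization, von Neumann entropy diffusion-time selection, potential
    distances, metric MDS), identifies recurrent brain states by k-means with
    elbow, silhouette and gap-statistic model selection, estimates per-subject
    and pooled state-transition matrices, and tests topography, transition and
    embedding structure against three permutation null models with a
    Shannon-entropy statistic. Ships a synthetic-data generator that plants
    known state topographies and a Markov transition chain so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
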