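Package: embedgcn
Title: Graph Convolutional Classification of Image Embeddings with
    Similarity Graphs and Particle Swarm Tuning
Version: 0.1.0
Authors@R:
    person("embedgcn", "developers", email = "embedgcn@example.org",
           role = c("aut", "cre"))
Description: Transductive multi-class classification of images represented
    by fixed CNN feature embeddings. Builds a dataset-level similarity graph
    (thresholded cosine k-nearest neighbours, self-loops, optional
    class-aware training edges), symmetrically normalizes the adjacency, and
    classifies nodes with a two-layer graph convolutional network trained by
    Adam with early stopping. Includes a particle-swarm hyperparameter
    tuner, a synthetic embedding generator with controllable cluster
    overlap, a full multi-class evaluation suite (confusion matrix,
    per-class and macro/weighted precision, recall and F1), a dense
    multilayer-perceptron baseline, and an end-to-end pipeline with a
    command-line entry point. Motivated by brain-tumour MRI triage
    (glioma / meningioma / pituitary / no-tumour) but agnostic to the
    embedding source.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rhdf5,
    png,
    jpeg,
    yaml
Config/testthat/edition: 3
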