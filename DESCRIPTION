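Package: latentreplay
Title: Privacy-Aware Domain-Incremental Learning with Generative Latent Replay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for domain-incremental continual learning on latent feature
    vectors extracted by a frozen backbone. Past tasks are summarised by
    K-means cluster centers and rehearsed through a kernel density estimate
    built over those centers (or, alternatively, per-domain Gaussian mixture
    models), so no raw training vectors need to be stored. A small
    fully-connected classifier head is trained sequentially over a task
    sequence with hybrid replay mini-batches and Kullback-Leibler
    distillation from the previous session's frozen model. Includes a
    synthetic benchmark generator with controllable between-domain shift,
    the standard continual-learning evaluation metrics (ACC, BWT, ILM)
    computed from the train-test accuracy matrix, and a command-line
    interface for simulating benchmarks, running strategies and scoring
    result matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
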