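Package: msfs
Title: Silhouette-Guided Feature Separability Regularization for EEG Transfer Learning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transfer learning for motor-imagery EEG decoding with a
    silhouette-driven feature-separability regularizer (MSFS). During
    target-subject fine-tuning, each feature dimension of the network's
    penultimate layer is pulled toward the batch feature value that
    maximizes its one-dimensional silhouette score, behind a hard gate
    that activates only once the batch cross-entropy falls below a
    threshold. Includes the vectorized target-position search with a
    brute-force oracle, approximate variants (candidate subsampling,
    top-K features), a compact trainable reference backbone with
    analytic gradients, the full pretrain/fine-tune leave-one-subject-out
    protocol with few-shot subsampling and ablation harnesses, trial
    epoching, an epoched-trial container, and a synthetic multi-subject
    EEG generator emulating event-related desynchronization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml, optparse, MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
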