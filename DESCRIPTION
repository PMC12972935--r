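Package: phqgad
Title: Multitask Text Models for Joint PHQ-9 and GAD-7 Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening comorbid depression and anxiety from short
    free-text responses. Implements a multitask transformer text model that
    jointly predicts PHQ-9 and GAD-7 scores as continuous values and as
    three-level severity classes through a shared encoder, an extra
    self-attention block, dual-feature fusion and four task heads; a weighted
    multitask objective combining mean-squared-error regression loss,
    class-weighted label-smoothed cross-entropy and L2 regularization; a full
    training protocol with cosine-annealed AdamW, stochastic depth, gradient
    noise, exponential-moving-average parameter smoothing and early stopping;
    a conditional variational autoencoder for minority-class text
    augmentation with generation-quality filters; a synthetic corpus
    generator with correlated scores and severity-coupled vocabulary; and a
    screening-metric evaluation and ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
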