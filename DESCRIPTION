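Package: critens
Title: Ensemble Metric-Learning Classification of Short Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Character-level ensemble classification for imbalanced short-text
    corpora such as clinical-trial eligibility criteria sentences. Single
    models embed characters, extract features with multi-width convolutions
    and masked max-pooling, and are trained with a combined objective of
    focal loss (down-weighting easy samples under class imbalance) and a
    pairwise metric-learning loss (shrinking intra-class and enforcing a
    margin on inter-class feature distances). Member softmax outputs are
    combined by soft voting. Includes a synthetic imbalanced-corpus
    generator, macro-F1 evaluation, model comparison by paired t-test, and a
    data-volume ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
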