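Package: her2mil
Title: Weakly Supervised HER2 Scoring of Immunohistochemistry Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the immunohistochemistry (IHC) score (0-3) and the binary
    HER2 status of HER2-stained tissue-microarray spot images under weak
    (spot-level) supervision. Implements attention-based multiple-instance
    learning over tile embeddings with hand-written forward and backward
    passes, a staining-intensity-only logistic baseline, Beer-Lambert optical
    density transforms, H-DAB colour deconvolution and Macenko stain
    estimation/normalization, the evaluation metrics used in HER2 scoring
    studies (balanced accuracy, support-weighted precision/recall/F1,
    one-vs-all ROC), attention and intensity heatmaps, and a synthetic
    tissue-spot generator with controllable intensity-coded and
    morphology-coded signals so the whole pipeline is trainable and testable
    at desk scale without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jpeg,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
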