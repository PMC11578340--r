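Package: cfrag
Title: Cell-Free DNA Fragmentomics for Chemotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("cfrag", "developers", email = "cfrag@example.org", role = c("aut", "cre"))
Description: Tools for analysing plasma cell-free DNA (cfDNA) fragmentation
    features in the context of neoadjuvant chemotherapy (NACT) response
    prediction. Implements post-alignment fragment filtering, 256-category
    4-mer 5' end-motif profiling with nonparametric differential motif
    calling and the motif-ratio statistic, promoter (transcription start
    site) coverage scores with differential gene calling, longitudinal
    cfDNA concentration analytics (the cfDNA ratio), RECIST-style tumour
    response labelling, immunohistochemistry scoring, and ROC/AUC based
    evaluation including a multiple-logistic clinical classifier. Ships a
    fully self-contained synthetic cohort generator with known ground
    truth so the entire pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    tools,
    jsonlite,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
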