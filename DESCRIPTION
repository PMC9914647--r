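Package: r4alzr
Title: Composite Scoring and Diagnostic Discrimination for the R4Alz-R
    Cognitive Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating composite diagnostic scores
    from the R4Alz-R neuropsychological battery (14 sub-scores spanning
    working memory, attentional control, inhibition/switching, cognitive
    flexibility and episodic memory). Implements mediation-based subtask
    selection (parallel two-mediator path models with bootstrap indirect
    effects for age and education), min-max normalization with score
    orientation, eight weighted total-score formulas (plain and squared sums,
    AUC and AUC-squared scaling, standard-deviation scaling), and empirical
    ROC analysis with Youden-index-optimal cutoffs for pairwise
    discrimination of healthy controls, subjective cognitive decline and
    mild cognitive impairment. Includes a seeded synthetic-cohort generator
    with a linear diagnosis-(age, education)-score path structure so the
    full pipeline is testable without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
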