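Package: glioscore
Title: Pathway Activation and Drug Efficiency Scoring for Glioblastoma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing newly diagnosed and recurrent
    glioblastoma transcriptomes: median-of-ratios library-size normalization,
    per-gene case-to-normal ratios (CNR) against a normal-brain reference,
    single-sample pathway activation levels (PAL) from a signed
    activator/repressor pathway database, AUC-based differential ranking of
    genes and pathways between disease stages, tissue/stem-cell-culture
    concordance, molecular subtype assignment, and balanced efficiency scores
    (BES) for ranking anticancer target drugs. Includes a seeded synthetic
    cohort generator emulating multi-region, longitudinally paired tumor
    sampling with matched stem-cell cultures, so every stage of the pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
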