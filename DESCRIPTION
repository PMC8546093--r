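Package: ehrCSD
Title: Causal Structure Discovery from Longitudinal EHR Event Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering causal graphs among disease-related
    events recorded in electronic health records. Longitudinal event and
    measurement tables are transformed into a two-cross-section panel of
    pre-existing and incident binary statuses, temporal precedence between
    event pairs is established with an exact discordant-pair binomial test,
    and a directed acyclic graph is built by precedence-constrained greedy
    search that scores candidate structures with an edge-penalised BIC over
    per-node logistic transition models. Includes bootstrap orientation
    stability, evidence-based precision and recall metrics, cross-cohort
    edge concordance, and a synthetic cohort generator with a known
    ground-truth transition graph for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
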