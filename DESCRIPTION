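Package: kgmine
Title: Literature Knowledge-Graph Mining for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and mines literature-derived biomedical knowledge graphs
    to rank drug-repurposing candidates for Alzheimer's disease and related
    dementias. Reads semantic predications in the SemMedDB PREDICATION-table
    dialect, filters them with a semantic-group blocklist and a composite of
    degree centrality and the G-squared log-likelihood-ratio association
    score, optionally calibrates triples with a pluggable binary relevance
    classifier, trains translational and bilinear knowledge-graph-embedding
    models (TransE, DistMult, ComplEx) from scratch with negative sampling
    and logistic loss, evaluates them by time-sliced link prediction (mean
    rank, mean reciprocal rank, Hits@k under raw and filtered protocols),
    and ranks candidate (drug, relation, disease) triples and entities.
    Includes a synthetic predication-corpus generator with planted,
    recoverable relational structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
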