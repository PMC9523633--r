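#' Semantic-type to semantic-group mapping
#'
#' A compact, editable subset of the UMLS Semantic Network grouping:
#' enough to cover the six generic groups removed by the default blocklist
#' (Activities & Behaviors, Concepts & Ideas, Objects, Occupations,
#' Organizations, Phenomena) plus the substantive groups a biomedical
#' knowledge graph keeps (Chemicals & Drugs, Disorders, Anatomy, Physiology,
#' Genes & Molecular Sequences, Living Beings, Devices, Procedures).
#' The full (licensed) Semantic Network is not bundled; pass your own
#' mapping for other vocabularies.
#'
#' @return A tibble with columns `semtype` (lowercase type code) and `group`.
#' @export
semantic_group_map <- function() {
  groups <- list(
    "Activities & Behaviors" = c("acty", "bhvr", "dora", "evnt", "gora",
                                 "inbe", "mcha", "ocac", "socb"),
    "Concepts & Ideas" = c("clas", "cnce", "ftcn", "grpa", "idcn", "inpr",
                           "lang", "qlco", "qnco", "rnlw", "spco", "tmco"),
    "Objects" = c("enty", "mnob", "phob"),
    "Occupations" = c("bmod", "ocdi"),
    "Organizations" = c("hcro", "orgt", "pros", "shro"),
    "Phenomena" = c("eehu", "hcpp", "labr", "npop", "phpr"),
    "Chemicals & Drugs" = c("aapp", "antb", "bacs", "bodm", "chem", "chvf",
                            "chvs", "clnd", "elii", "enzy", "hops", "horm",
                            "imft", "irda", "inch", "nnon", "orch", "phsu",
                            "vita", "food"),
    "Disorders" = c("acab", "anab", "cgab", "comd", "dsyn", "emod", "fndg",
                    "inpo", "mobd", "neop", "patf", "sosy"),
    "Genes & Molecular Sequences" = c("amas", "crbs", "gngm", "mosq", "nusq"),
    "Anatomy" = c("anst", "blor", "bpoc", "bsoj", "bdsu", "cell", "celc",
                  "emst", "ffas", "tisu"),
    "Physiology" = c("celf", "clna", "menp", "moft", "orgf", "ortf", "phsf"),
    "Living Beings" = c("aggp", "amph", "anim", "arch", "bact", "bird",
                        "euka", "fish", "fngs", "grup", "humn", "mamm",
                        "orgm", "plnt", "podg", "popg", "prog", "rept",
                        "virs"),
    "Devices" = c("drdd", "medd", "resd"),
    "Procedures" = c("diap", "edac", "hlca", "lbpr", "mbrt", "resa", "topp")
  )
  tibble(
    semtype = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
}

#' Default blocklist of generic semantic groups
#'
#' Generic biomedical concept groups whose predications add noise rather than
#' repurposing signal and are removed before scoring.
#'
#' @return Character vector of semantic-group labels.
#' @export
default_blocklist <- function() {
  c("Activities & Behaviors", "Concepts & Ideas", "Objects",
    "Occupations", "Organizations", "Phenomena")
}

#' Remove predications involving blocked semantic groups
#'
#' A predication is removed when its subject's or object's semantic group is
#' on the blocklist. Semantic types absent from `group_map` pass through
#' (and are reported once via a message).
#'
#' @param records Predication tibble.
#' @param blocklist Character vector of semantic-group labels to remove;
#'   defaults to [default_blocklist()].
#' @param group_map Tibble with columns `semtype`, `group`; defaults to
#'   [semantic_group_map()].
#' @return A list with `retained` and `removed` predication tibbles
#'   (`nrow(retained) + nrow(removed)` always equals the input row count).
#' @export
semantic_type_filter <- function(records, blocklist = default_blocklist(),
                                 group_map = semantic_group_map()) {
  assert_columns(records, c("subject_semtype", "object_semtype"), "records")
  assert_columns(group_map, c("semtype", "group"), "group_map")
  lookup <- setNames(group_map$group, group_map$semtype)
  sg <- unname(lookup[records$subject_semtype])
  og <- unname(lookup[records$object_semtype])
  unmapped <- unique(c(records$subject_semtype[is.na(sg)],
                       records$object_semtype[is.na(og)]))
  unmapped <- setdiff(unmapped, NA)
  if (length(unmapped) > 0) {
    inform(sprintf("semantic_type_filter: %d unmapped semantic type(s) pass through: %s",
                   length(unmapped), paste(head(unmapped, 5), collapse = ", ")))
  }
  blocked <- (!is.na(sg) & sg %in% blocklist) | (!is.na(og) & og %in% blocklist)
  list(retained = records[!blocked, , drop = FALSE],
       removed = records[blocked, , drop = FALSE])
}

#' Degree centrality from the graph adjacency matrix
#'
#' For each entity i, the out-degree A_out(i) is the i-th row sum of the
#' adjacency matrix M and the in-degree A_in(i) the i-th column sum.
#' With the default count adjacency these are the numbers of distinct
#' triples in which the entity appears as head, respectively tail.
#'
#' @param graph A `knowledge_graph` from [build_graph()].
#' @return A tibble with columns `entity`, `a_out`, `a_in`.
#' @export
degree_centrality <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  tibble(
    entity = graph$entities,
    a_out = as.numeric(Matrix::rowSums(graph$adjacency)),
    a_in = as.numeric(Matrix::colSums(graph$adjacency))
  )
}

#' Independence expectations for a contingency table
#'
#' For a k-dimensional table of observed counts O with grand total N, the
#' expected count of a cell under full independence is the product of that
#' cell's k marginal sums divided by N^(k-1). Expected counts sum back to N.
#'
#' @param observed A numeric array (or matrix / vector) of non-negative
#'   counts with positive grand total.
#' @return An object of class `contingency_table`: list with `observed`,
#'   `expected` (same shape), and `total`.
#' @export
independence_expectation <- function(observed) {
  observed <- as.array(observed)
  if (any(observed < 0)) abort("observed counts must be non-negative")
  total <- sum(observed)
  if (total <= 0) abort("grand total must be positive")
  k <- length(dim(observed))
  margins <- lapply(seq_len(k), function(ax) apply(observed, ax, sum))
  expected <- array(Reduce(`%o%`, margins) / total^(k - 1), dim = dim(observed))
  structure(list(observed = observed, expected = expected, total = total),
            class = "contingency_table")
}

#' G-squared (log-likelihood ratio) association statistic
#'
#' Computes G^2 = 2 * sum over cells of O * log(O / E), where O is the
#' observed table and E the independence expectation; cells with O = 0
#' contribute zero (the x log x limit). G^2 is zero exactly when the table
#' is independent and grows with the strength of association.
#'
#' @param table A `contingency_table` from [independence_expectation()],
#'   or a raw count array (the expectation is then computed first).
#' @return A non-negative number.
#' @export
g_squared <- function(table) {
  if (!inherits(table, "contingency_table")) {
    table <- independence_expectation(table)
  }
  o <- as.numeric(table$observed)
  e <- as.numeric(table$expected)
  pos <- o > 0
  if (any(pos & e <= 0)) abort("observed > 0 where expected = 0: G^2 undefined")
  g2 <- 2 * sum(o[pos] * log(o[pos] / e[pos]))
  max(g2, 0)
}

# Vectorized G^2 for many 2x2 tables [[a, b], [c, d]] given as columns.
g2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  xlogx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  g2 <- 2 * (xlogx(a, r1 * c1 / n) + xlogx(b, r1 * c2 / n) +
               xlogx(c, r2 * c1 / n) + xlogx(d, r2 * c2 / n))
  pmax(g2, 0)
}

#' Subject--object association strength over predication mentions
#'
#' For every (subject, object) pair observed in the corpus, builds the 2x2
#' contingency table of mention counts
#' \[n(s,o), n(s, not o); n(not s, o), n(not s, not o)\]
#' over all predication rows (pre-deduplication, so repeated assertions in
#' the literature strengthen the association) and returns its G-squared
#' statistic.
#'
#' @param records Predication tibble with at least one row.
#' @return A tibble with columns `subject_id`, `object_id`, `n_mentions`,
#'   `g2`.
#' @export
pair_association <- function(records) {
  assert_columns(records, c("subject_id", "object_id"), "records")
  if (nrow(records) == 0) abort("pair_association needs at least one record")
  pairs <- records |> count(.data$subject_id, .data$object_id, name = "n_mentions")
  subj_tot <- records |> count(.data$subject_id, name = "n_subj")
  obj_tot <- records |> count(.data$object_id, name = "n_obj")
  n <- nrow(records)
  pairs |>
    left_join(subj_tot, by = "subject_id") |>
    left_join(obj_tot, by = "object_id") |>
    mutate(
      g2 = g2_2x2(.data$n_mentions,
                  .data$n_subj - .data$n_mentions,
                  .data$n_obj - .data$n_mentions,
                  n - .data$n_subj - .data$n_obj + .data$n_mentions)
    ) |>
    select("subject_id", "object_id", "n_mentions", "g2")
}

#' Composite triple score from centrality and association
#'
#' Each triple gets three raw components -- the subject's out-degree, the
#' object's in-degree, and the subject--object G-squared association --
#' each min--max normalized to \[0, 1\] across all triples (a constant
#' component normalizes to all zeros) and summed into a composite in
#' \[0, 3\].
#'
#' @param triples Tibble with columns `head`, `relation`, `tail`.
#' @param centrality Tibble from [degree_centrality()] covering every head
#'   and tail.
#' @param association Tibble from [pair_association()] covering every
#'   (head, tail) pair.
#' @param endpoint `"directional"` (default) uses the subject's A_out and
#'   the object's A_in; `"total"` uses A_in + A_out for both endpoints.
#' @return The input triples with columns `a_out_s`, `a_in_o`, `g2`,
#'   `norm_a_out_s`, `norm_a_in_o`, `norm_g2`, `composite`.
#' @export
composite_scores <- function(triples, centrality, association,
                             endpoint = c("directional", "total")) {
  endpoint <- match.arg(endpoint)
  assert_columns(triples, c("head", "relation", "tail"), "triples")
  assert_columns(centrality, c("entity", "a_out", "a_in"), "centrality")
  assert_columns(association, c("subject_id", "object_id", "g2"), "association")
  hi <- match(triples$head, centrality$entity)
  ti <- match(triples$tail, centrality$entity)
  if (anyNA(hi) || anyNA(ti)) abort("triple endpoint missing from centrality table")
  ai <- match(triple_key(triples$head, "", triples$tail),
              triple_key(association$subject_id, "", association$object_id))
  if (anyNA(ai)) abort("(head, tail) pair missing from association table")
  if (endpoint == "directional") {
    a_out_s <- centrality$a_out[hi]
    a_in_o <- centrality$a_in[ti]
  } else {
    a_out_s <- centrality$a_out[hi] + centrality$a_in[hi]
    a_in_o <- centrality$a_out[ti] + centrality$a_in[ti]
  }
  triples |>
    mutate(
      a_out_s = a_out_s,
      a_in_o = a_in_o,
      g2 = association$g2[ai],
      norm_a_out_s = minmax(a_out_s),
      norm_a_in_o = minmax(a_in_o),
      norm_g2 = minmax(.data$g2),
      composite = .data$norm_a_out_s + .data$norm_a_in_o + .data$norm_g2
    )
}

#' Keep the top-k scored triples, always preserving whitelisted concepts
#'
#' Triples whose head or tail is on the whitelist (e.g. Alzheimer's-disease
#' concepts) are retained unconditionally. The remaining slots, k minus the
#' number of whitelist-retained triples (floored at zero), are filled by the
#' best composite scores. Ties break deterministically: score, then
#' lexicographic (head, relation, tail).
#'
#' @param scored Tibble from [composite_scores()] (must carry `composite`).
#' @param k Total number of triples to keep (whitelisted triples can push
#'   the result above k).
#' @param whitelist Character vector of concept identifiers to preserve.
#' @param keep `"high"` (default) keeps the highest composites, `"low"` the
#'   lowest.
#' @return The retained triples, a tibble.
#' @export
select_top_k <- function(scored, k, whitelist = character(), keep = c("high", "low")) {
  keep <- match.arg(keep)
  assert_columns(scored, c("head", "relation", "tail", "composite"), "scored")
  if (k < 0) abort("k must be non-negative")
  white <- scored$head %in% whitelist | scored$tail %in% whitelist
  rest <- scored[!white, , drop = FALSE]
  slots <- max(k - sum(white), 0)
  ord <- order(if (keep == "high") -rest$composite else rest$composite,
               rest$head, rest$relation, rest$tail)
  bind_rows(scored[white, , drop = FALSE], rest[head(ord, slots), , drop = FALSE])
}

#' Bundled default whitelist of Alzheimer's-disease concepts
#'
#' A small set of AD-related UMLS concept identifiers (the disease itself
#' plus onset/familial variants and dementia concepts) used as the default
#' whitelist for score filtering and as ranking tails. Replace with a fuller
#' list for production corpora via [read_concept_list()].
#'
#' @return Character vector of concept identifiers.
#' @export
default_ad_whitelist <- function() {
  read_concept_list(system.file("extdata", "ad_concepts.txt",
                                package = "kgmine", mustWork = TRUE))
}

#' Read a newline-delimited concept or group list
#'
#' Whitelists, blocklists, and candidate-category lists are plain text files
#' with one label per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_concept_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("concept list not found: %s", path))
  x <- trimws(readr::read_lines(path, progress = FALSE))
  x[x != "" & !startsWith(x, "#")]
}
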