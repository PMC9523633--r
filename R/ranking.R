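#' Define a candidate category for repurposing
#'
#' A category is the set of concepts whose repurposing potential is being
#' assessed (clinical drugs, chemicals, or dietary supplements) together
#' with the relations scored against the disease concepts. Drugs and
#' chemicals default to the treatment/prevention relations; dietary
#' supplements default to the broader affect relation, where direct
#' treatment links are rarely asserted in the literature.
#'
#' @param name Category name: `"drug"`, `"chemical"`, `"supplement"`, or a
#'   custom label.
#' @param head_ids Non-empty character vector of candidate concept
#'   identifiers.
#' @param relations Relation labels to score; defaults by category name.
#' @return An object of class `candidate_category`.
#' @export
candidate_category <- function(name, head_ids, relations = NULL) {
  if (length(head_ids) == 0) abort("head_ids must be non-empty")
  if (is.null(relations)) {
    relations <- switch(name,
      drug = c("TREATS", "PREVENTS"),
      chemical = c("TREATS", "PREVENTS"),
      supplement = "AFFECTS",
      abort("custom categories must specify their relations")
    )
  }
  structure(list(name = name, head_ids = unique(head_ids),
                 relations = unique(relations)),
            class = "candidate_category")
}

#' @exportS3Method base::print
print.candidate_category <- function(x, ...) {
  cat(sprintf("<candidate_category> %s: %d heads x relations {%s}\n",
              x$name, length(x$head_ids), paste(x$relations, collapse = ", ")))
  invisible(x)
}

#' Enumerate candidate triples for a category
#'
#' Forms the Cartesian product of the category's head concepts, its
#' relations, and the disease tail concepts, in deterministic
#' (head, relation, tail) order. Heads, relations, or tails unknown to the
#' model are skipped with a message.
#'
#' @param category A `candidate_category`.
#' @param ad_tails Character vector of disease concept identifiers (the
#'   AD-related whitelist).
#' @param model A `kge_model` supplying the entity/relation universe.
#' @return A tibble with columns `head`, `relation`, `tail`.
#' @export
enumerate_candidates <- function(category, ad_tails, model) {
  stopifnot(inherits(category, "candidate_category"), inherits(model, "kge_model"))
  heads <- intersect(category$head_ids, model$entities)
  rels <- intersect(category$relations, model$relations)
  tails <- intersect(ad_tails, model$entities)
  skipped <- (length(category$head_ids) - length(heads)) +
    (length(category$relations) - length(rels)) +
    (length(ad_tails) - length(tails))
  if (skipped > 0) {
    inform(sprintf("enumerate_candidates: skipped %d concept(s)/relation(s) absent from the model", skipped))
  }
  if (length(heads) == 0 || length(rels) == 0 || length(tails) == 0) {
    abort("no candidate triples: empty heads, relations, or tails after skipping")
  }
  tidyr::expand_grid(head = sort(heads), relation = sort(rels),
                     tail = sort(tails))
}

#' Score and rank candidate triples
#'
#' Scores every candidate with the trained model and ranks them within each
#' relation, descending by score with a deterministic lexicographic
#' tie-break. Candidates already asserted in the training triples are
#' flagged (`novel = FALSE`) and, with `novel_only = TRUE` (the default,
#' since repurposing looks for links the literature has not yet made),
#' dropped before ranking.
#'
#' @param model A `kge_model`.
#' @param candidates Tibble from [enumerate_candidates()].
#' @param training_triples Tibble of triples the model was trained on (used
#'   for the novelty flag); `NULL` marks everything novel.
#' @param novel_only Drop known triples before ranking (default `TRUE`).
#' @return A tibble of class `candidate_predictions`: `head`, `relation`,
#'   `tail`, `score`, `novel`, and `rank` (1-based within relation).
#' @export
score_and_rank <- function(model, candidates, training_triples = NULL,
                           novel_only = TRUE) {
  assert_columns(candidates, c("head", "relation", "tail"), "candidates")
  known <- if (is.null(training_triples)) character() else
    triple_key(training_triples$head, training_triples$relation,
               training_triples$tail)
  out <- candidates |>
    mutate(
      score = kge_score(model, .data$head, .data$relation, .data$tail),
      novel = !(triple_key(.data$head, .data$relation, .data$tail) %in% known)
    )
  if (novel_only) out <- out[out$novel, , drop = FALSE]
  out <- out |>
    arrange(.data$relation, desc(.data$score), .data$head, .data$tail) |>
    group_by(.data$relation) |>
    mutate(rank = row_number()) |>
    ungroup()
  class(out) <- c("candidate_predictions", class(out))
  out
}

#' Rank entities by appearances among top-scored triples
#'
#' The entity-level view behind per-category ranking tables: within every
#' (relation, disease-tail) list, take the `top_n` best-scored candidate
#' triples, then count how often each head entity appears across those
#' lists, per relation. An entity connected to many disease concepts
#' accumulates a high frequency (at most the number of tails).
#'
#' @param predictions A `candidate_predictions` tibble from
#'   [score_and_rank()].
#' @param top_n Per-(relation, tail) list length (default 10).
#' @return A tibble with columns `relation`, `head`, `frequency`, ordered by
#'   descending frequency (ties by head label) within relation.
#' @export
frequency_rank <- function(predictions, top_n = 10) {
  assert_columns(predictions, c("head", "relation", "tail", "score"), "predictions")
  predictions |>
    group_by(.data$relation, .data$tail) |>
    arrange(desc(.data$score), .data$head, .by_group = TRUE) |>
    slice_head(n = top_n) |>
    group_by(.data$relation) |>
    count(.data$head, name = "frequency") |>
    arrange(desc(.data$frequency), .data$head, .by_group = TRUE) |>
    ungroup() |>
    select("relation", "head", "frequency")
}

#' Export candidate rankings as CSV reports
#'
#' Writes the triple-level ranking (`triple_rankings.csv`: head, relation,
#' tail, score, rank, novel) and the entity frequency ranking
#' (`entity_frequencies.csv`). Output is deterministic given its inputs.
#'
#' @param predictions A `candidate_predictions` tibble.
#' @param frequencies A tibble from [frequency_rank()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_rankings <- function(predictions, frequencies, dir) {
  if (nrow(predictions) == 0) abort("no predictions to export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    triples = file.path(dir, "triple_rankings.csv"),
    entities = file.path(dir, "entity_frequencies.csv")
  )
  readr::write_csv(predictions[, c("head", "relation", "tail", "score",
                                   "rank", "novel")], paths[["triples"]],
                   progress = FALSE)
  readr::write_csv(frequencies, paths[["entities"]], progress = FALSE)
  invisible(paths)
}
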