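#' Rank the true entity of a link-prediction query
#'
#' Scores every candidate substitution of the chosen side of the triple and
#' ranks the true entity. The rank is `1 + (# candidates scoring strictly
#' higher) + (# exact ties, excluding the true entity) / 2` -- the mean rank
#' of the tie block, which avoids order-of-enumeration bias. Under the
#' `filtered` protocol, candidates that would form a known true triple
#' (other than the query itself) are removed before ranking.
#'
#' @param model A `kge_model`.
#' @param head,relation,tail The query triple (labels or indices; scalars).
#' @param side Which slot to corrupt: `"head"` or `"tail"`.
#' @param protocol `"filtered"` (default) or `"raw"`.
#' @param known_triples Tibble of known true triples (`head`, `relation`,
#'   `tail`) used by the filtered protocol; typically all train + validation
#'   + test triples.
#' @return The rank, a number >= 1.
#' @export
rank_query <- function(model, head, relation, tail, side = c("tail", "head"),
                       protocol = c("filtered", "raw"), known_triples = NULL) {
  side <- match.arg(side)
  protocol <- match.arg(protocol)
  h <- resolve_entities(model, head, "head entity")
  r <- resolve_relations(model, relation)
  t <- resolve_entities(model, tail, "tail entity")
  known_keys <- known_keys_for(model, known_triples)
  rank_query_idx(model, h, r, t, side, protocol, known_keys)
}

known_keys_for <- function(model, known_triples) {
  if (is.null(known_triples) || nrow(known_triples) == 0) return(character())
  triple_key(resolve_entities(model, known_triples$head, "head entity"),
             resolve_relations(model, known_triples$relation),
             resolve_entities(model, known_triples$tail, "tail entity"))
}

rank_query_idx <- function(model, h, r, t, side, protocol, known_keys) {
  scores <- kge_score_all(model, side, h, r, t)
  true_idx <- if (side == "tail") t else h
  keep <- rep(TRUE, length(scores))
  if (protocol == "filtered" && length(known_keys) > 0) {
    cand <- seq_along(scores)
    keys <- if (side == "tail") triple_key(h, r, cand) else triple_key(cand, r, t)
    keep <- !(keys %in% known_keys)
    keep[true_idx] <- TRUE
  }
  s_true <- scores[true_idx]
  s <- scores[keep]
  higher <- sum(s > s_true)
  ties <- sum(s == s_true) - 1
  1 + higher + ties / 2
}

new_ranking_metrics <- function(ranks, ks, protocol, sides) {
  hits <- vapply(ks, function(k) mean(ranks <= k), numeric(1))
  structure(
    list(mr = mean(ranks), mrr = mean(1 / ranks),
         hits = setNames(hits, paste0("hits@", ks)),
         n_queries = length(ranks), protocol = protocol, sides = sides,
         ranks = ranks),
    class = "ranking_metrics"
  )
}

#' @exportS3Method base::print
print.ranking_metrics <- function(x, ...) {
  cat(sprintf("<ranking_metrics> %d queries (%s, sides: %s)\n",
              x$n_queries, x$protocol, x$sides))
  cat(sprintf("  MR %.2f | MRR %.3f | %s\n", x$mr, x$mrr,
              paste(sprintf("%s %.3f", names(x$hits), x$hits), collapse = " | ")))
  invisible(x)
}

#' @rdname kge_evaluate
#' @param x A `ranking_metrics` object.
#' @param ... Unused.
#' @export
tidy.ranking_metrics <- function(x, ...) {
  tibble(metric = c("mr", "mrr", names(x$hits)),
         value = c(x$mr, x$mrr, unname(x$hits)))
}

#' @rdname kge_evaluate
#' @export
glance.ranking_metrics <- function(x, ...) {
  out <- tibble(mr = x$mr, mrr = x$mrr, n_queries = x$n_queries,
                protocol = x$protocol, sides = x$sides)
  for (nm in names(x$hits)) out[[nm]] <- unname(x$hits[nm])
  out
}

#' Link-prediction ranking metrics (MR, MRR, Hits@k)
#'
#' Evaluates a trained model on a set of test triples. With `sides =
#' "both"` each triple contributes one head-corruption query and one
#' tail-corruption query. MR is the mean rank, MRR the mean reciprocal
#' rank, and Hits@k the fraction of queries whose true entity ranks within
#' the top k.
#'
#' @param model A `kge_model`.
#' @param test Tibble of evaluation triples (`head`, `relation`, `tail`).
#' @param known_triples Known true triples for the filtered protocol.
#' @param ks Cutoffs for Hits@k (default 1, 3, 10).
#' @param protocol `"filtered"` (default) or `"raw"`.
#' @param sides `"both"` (default), `"head"`, or `"tail"`.
#' @return An object of class `ranking_metrics` (use [tidy()] / [glance()]
#'   for tibble views; the per-query ranks are kept in `$ranks`).
#' @export
kge_evaluate <- function(model, test, known_triples = NULL, ks = c(1, 3, 10),
                         protocol = c("filtered", "raw"),
                         sides = c("both", "head", "tail")) {
  protocol <- match.arg(protocol)
  sides <- match.arg(sides)
  assert_columns(test, c("head", "relation", "tail"), "test")
  if (nrow(test) == 0) abort("test set is empty")
  h <- resolve_entities(model, test$head, "head entity")
  r <- resolve_relations(model, test$relation)
  t <- resolve_entities(model, test$tail, "tail entity")
  known_keys <- known_keys_for(model, known_triples)
  query_sides <- switch(sides, both = c("head", "tail"), head = "head",
                        tail = "tail")
  ranks <- unlist(lapply(query_sides, function(sd) {
    vapply(seq_len(nrow(test)), function(i) {
      rank_query_idx(model, h[i], r[i], t[i], sd, protocol, known_keys)
    }, numeric(1))
  }))
  new_ranking_metrics(ranks, ks, protocol, sides)
}

#' Time-sliced link-prediction evaluation
#'
#' The literature-mining validation protocol: deduplicate the predications,
#' split the triples by first publication year, train only on the training
#' slice, and measure whether the model ranks triples first published in
#' later slices highly. Validation- and test-slice triples whose entities or
#' relations never occur in the training slice cannot be ranked and are
#' excluded (counted in the result). The filtered protocol removes all known
#' triples (any slice) from the candidate lists.
#'
#' @param predications Predication tibble with years.
#' @param train_before,valid_through Split years; see [temporal_split()].
#' @param family,... Passed to [kge_train()] (e.g. `dim`, `epochs`, `seed`).
#' @param ks,protocol As in [kge_evaluate()].
#' @return A list with the trained `model`, the `split`, and
#'   `ranking_metrics` for `validation` and `test` slices (plus per-slice
#'   counts of unrankable triples).
#' @export
time_slice_evaluate <- function(predications, train_before = 2019,
                                valid_through = 2020,
                                family = kge_families, ks = c(1, 3, 10),
                                protocol = c("filtered", "raw"), ...) {
  family <- match.arg(family)
  protocol <- match.arg(protocol)
  triples <- deduplicate_predications(predications)
  split <- temporal_split(triples, train_before, valid_through)
  if (nrow(split$train) == 0) abort("degenerate split: empty training slice")
  if (nrow(split$test) == 0 && nrow(split$validation) == 0) {
    abort("degenerate split: no evaluation triples after the boundary")
  }
  graph <- build_graph(split$train)
  known <- dplyr::bind_rows(split$train, split$validation, split$test)
  model <- kge_train(graph, family = family, ...)
  eval_slice <- function(slice) {
    rankable <- slice$head %in% graph$entities &
      slice$tail %in% graph$entities &
      slice$relation %in% graph$relations
    known_rankable <- known[known$head %in% graph$entities &
                              known$tail %in% graph$entities &
                              known$relation %in% graph$relations, ]
    if (!any(rankable)) {
      return(list(metrics = NULL, n_unrankable = sum(!rankable)))
    }
    list(metrics = kge_evaluate(model, slice[rankable, ], known_rankable,
                                ks = ks, protocol = protocol),
         n_unrankable = sum(!rankable))
  }
  va <- eval_slice(split$validation)
  te <- eval_slice(split$test)
  list(model = model, split = split,
       validation = va$metrics, test = te$metrics,
       n_unrankable = c(validation = va$n_unrankable, test = te$n_unrankable))
}
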