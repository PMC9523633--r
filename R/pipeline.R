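#' Configuration for the end-to-end mining pipeline
#'
#' Bundles every stage parameter: filtering (blocklist, whitelist, top-k),
#' relevance calibration (scorer and threshold), time-slice years, embedding
#' training, evaluation protocol, and candidate ranking. One global seed
#' fans out to stage-specific derived seeds so each stage is independently
#' reproducible.
#'
#' @param blocklist Semantic groups to remove; [default_blocklist()].
#' @param group_map Semantic-type grouping table; [semantic_group_map()].
#' @param whitelist Disease (AD-related) concept identifiers preserved by the
#'   score filter and used as ranking tails.
#' @param top_k Number of triples the composite-score filter keeps (the
#'   whitelist is kept on top of this).
#' @param keep Which end of the composite score to keep (`"high"`/`"low"`).
#' @param adjacency `"count"` or `"binary"` adjacency for centrality.
#' @param scorer Relevance scorer (a `baseline_classifier` or function), or
#'   `NULL` to skip the calibration stage.
#' @param threshold Relevance-retention threshold in \[0, 1\].
#' @param train_before,valid_through Time-slice years; see [temporal_split()].
#' @param family,dim,learning_rate,epochs,batch_size,negatives,norm_order
#'   Embedding training parameters; see [kge_train()].
#' @param protocol Ranking protocol, `"filtered"` or `"raw"`.
#' @param ks Hits@k cutoffs.
#' @param categories List of [candidate_category()] objects to rank (may be
#'   empty).
#' @param top_n Per-(relation, tail) list length for [frequency_rank()].
#' @param novel_only Rank only triples absent from training.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(blocklist = default_blocklist(),
                            group_map = semantic_group_map(),
                            whitelist = character(),
                            top_k = Inf, keep = "high", adjacency = "count",
                            scorer = NULL, threshold = 0.5,
                            train_before = 2019, valid_through = 2020,
                            family = "transe", dim = 32,
                            learning_rate = 0.01, epochs = 200,
                            batch_size = 512, negatives = 1, norm_order = 2,
                            protocol = "filtered", ks = c(1, 3, 10),
                            categories = list(), top_n = 10,
                            novel_only = TRUE, seed = 42) {
  structure(
    list(blocklist = blocklist, group_map = group_map, whitelist = whitelist,
         top_k = top_k, keep = keep, adjacency = adjacency, scorer = scorer,
         threshold = threshold, train_before = train_before,
         valid_through = valid_through, family = family, dim = dim,
         learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, negatives = negatives,
         norm_order = norm_order, protocol = protocol, ks = ks,
         categories = categories, top_n = top_n, novel_only = novel_only,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Run the literature-mining pipeline end to end
#'
#' Stage order: read (already-parsed predications in, so the caller controls
#' IO) -> semantic-group blocklist filter -> composite-score filter (degree
#' centrality + G-squared association, whitelist-preserving top-k) ->
#' optional relevance-classifier filter -> deduplication -> temporal split
#' -> embedding training on the training slice -> link-prediction evaluation
#' on the validation and test slices -> candidate ranking. Every filtering
#' stage's input/retained/removed counts are recorded; retained + removed
#' always equals the input.
#'
#' @param predications Predication tibble (see [read_predications()]).
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_run`: `stages` (count tibble), `split`,
#'   `model`, `validation` / `test` ranking metrics, `rankings` (per
#'   category: predictions and frequencies), and `config`.
#' @export
run_pipeline <- function(predications, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  note <- function(stage, n_in, n_kept) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_retained = n_kept, n_removed = n_in - n_kept
    )
  }
  n0 <- nrow(predications)

  sem <- semantic_type_filter(predications, config$blocklist, config$group_map)
  note("semantic_type_filter", n0, nrow(sem$retained))

  current <- sem$retained
  if (nrow(current) == 0) abort("pipeline aborted at semantic_type_filter: no predications retained")

  if (is.finite(config$top_k)) {
    triples0 <- deduplicate_predications(current)
    graph0 <- build_graph(triples0, adjacency = config$adjacency)
    scored <- composite_scores(triples0, degree_centrality(graph0),
                               pair_association(current))
    kept_triples <- select_top_k(scored, config$top_k, config$whitelist,
                                 keep = config$keep)
    kept_keys <- triple_key(kept_triples$head, kept_triples$relation,
                            kept_triples$tail)
    keep <- triple_key(current$subject_id, current$predicate,
                       current$object_id) %in% kept_keys
    note("score_filter", nrow(current), sum(keep))
    current <- current[keep, , drop = FALSE]
  } else {
    note("score_filter", nrow(current), nrow(current))
  }
  if (nrow(current) == 0) abort("pipeline aborted at score_filter: no predications retained")

  if (!is.null(config$scorer)) {
    rel <- apply_relevance_filter(current, config$scorer, config$threshold)
    note("relevance_filter", nrow(current), nrow(rel$retained))
    current <- rel$retained
  } else {
    note("relevance_filter", nrow(current), nrow(current))
  }
  if (nrow(current) == 0) abort("pipeline aborted at relevance_filter: no predications retained")

  triples <- deduplicate_predications(current)
  note("deduplicate", nrow(current), nrow(triples))

  split <- temporal_split(triples, config$train_before, config$valid_through)
  if (nrow(split$train) == 0) abort("pipeline aborted at training: empty graph (no training-slice triples)")
  graph <- build_graph(split$train, adjacency = config$adjacency)
  if (length(graph$entities) < 2) abort("pipeline aborted at training: empty graph")

  model <- kge_train(graph, family = config$family, dim = config$dim,
                     learning_rate = config$learning_rate,
                     epochs = config$epochs, batch_size = config$batch_size,
                     negatives = config$negatives,
                     norm_order = config$norm_order,
                     seed = derive_seed(config$seed, "train"))

  known <- bind_rows(split$train, split$validation, split$test)
  eval_slice <- function(slice) {
    ok <- slice$head %in% graph$entities & slice$tail %in% graph$entities &
      slice$relation %in% graph$relations
    if (!any(ok)) return(NULL)
    kge_evaluate(model, slice[ok, ],
                 known[known$head %in% graph$entities &
                         known$tail %in% graph$entities &
                         known$relation %in% graph$relations, ],
                 ks = config$ks, protocol = config$protocol)
  }
  validation <- eval_slice(split$validation)
  test <- eval_slice(split$test)

  rankings <- lapply(config$categories, function(cat) {
    cands <- enumerate_candidates(cat, config$whitelist, model)
    preds <- score_and_rank(model, cands, split$train,
                            novel_only = config$novel_only)
    list(category = cat$name, predictions = preds,
         frequencies = frequency_rank(preds, config$top_n))
  })

  structure(
    list(stages = bind_rows(stages), split = split, model = model,
         validation = validation, test = test, rankings = rankings,
         config = config),
    class = "pipeline_run"
  )
}

#' @exportS3Method base::print
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  print(x$split)
  if (!is.null(x$test)) {
    cat("test slice: ")
    print(x$test)
  }
  invisible(x)
}

#' Write a pipeline run report as JSON
#'
#' The report carries the per-stage counts, split sizes, ranking metrics,
#' and a config echo (seed, years, training hyper-parameters), enough to
#' re-run the pipeline identically.
#'
#' @param run A `pipeline_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "pipeline_run"))
  cfg <- run$config
  metrics_of <- function(m) if (is.null(m)) NULL else
    c(list(mr = m$mr, mrr = m$mrr, n_queries = m$n_queries), as.list(m$hits))
  report <- list(
    stages = run$stages,
    split = list(train = nrow(run$split$train),
                 validation = nrow(run$split$validation),
                 test = nrow(run$split$test),
                 excluded_missing_year = run$split$n_excluded),
    metrics = list(validation = metrics_of(run$validation),
                   test = metrics_of(run$test)),
    config = list(seed = cfg$seed, family = cfg$family, dim = cfg$dim,
                  learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                  batch_size = cfg$batch_size, negatives = cfg$negatives,
                  norm_order = cfg$norm_order, top_k = cfg$top_k,
                  keep = cfg$keep, adjacency = cfg$adjacency,
                  threshold = cfg$threshold, protocol = cfg$protocol,
                  train_before = cfg$train_before,
                  valid_through = cfg$valid_through, top_n = cfg$top_n,
                  novel_only = cfg$novel_only,
                  blocklist = cfg$blocklist, whitelist = cfg$whitelist)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
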