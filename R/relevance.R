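#' Build the classifier text input for predications
#'
#' Deterministic template joining subject name, predicate, object name, and
#' the source sentence with the `" [SEP] "` separator, mirroring the input a
#' transformer-based relevance classifier consumes. A missing sentence leaves
#' the final segment empty.
#'
#' @param records Predication tibble (needs `subject_name`, `predicate`,
#'   `object_name`, `sentence`).
#' @return Character vector, one text per record.
#' @export
build_classifier_input <- function(records) {
  assert_columns(records, c("subject_name", "predicate", "object_name"), "records")
  sentence <- if ("sentence" %in% names(records)) records$sentence else NA_character_
  sentence <- ifelse(is.na(sentence), "", sentence)
  paste(records$subject_name, records$predicate, records$object_name, sentence,
        sep = " [SEP] ")
}

tokenize_texts <- function(texts) {
  lapply(strsplit(tolower(texts), "[^a-z0-9']+"), function(x) unique(x[x != ""]))
}

token_matrix <- function(tokens, vocab) {
  i <- rep.int(seq_along(tokens), lengths(tokens))
  j <- match(unlist(tokens), vocab)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(tokens), length(vocab)))
}

#' Train the built-in baseline relevance classifier
#'
#' A ridge-penalized logistic regression on binary token-presence features,
#' the package's lightweight stand-in for an externally fine-tuned
#' transformer scorer. Any function mapping texts to probabilities in
#' \[0, 1\] can replace it throughout the pipeline (see
#' [apply_relevance_filter()]).
#'
#' @param data Tibble with columns `text` and `label` (0/1); both classes
#'   must be present.
#' @param seed Integer seed (training is deterministic given the seed).
#' @param lambda Ridge penalty (default 0.01).
#' @return An object of class `baseline_classifier` with a [predict()]
#'   method mapping character texts to probabilities.
#' @export
train_baseline_classifier <- function(data, seed = 1, lambda = 0.01) {
  assert_columns(data, c("text", "label"), "data")
  y <- as.integer(data$label)
  if (!all(y %in% c(0L, 1L))) abort("labels must be 0 or 1")
  if (length(unique(y)) < 2) abort("both classes must be present in the training data")
  set.seed(seed)
  tokens <- tokenize_texts(data$text)
  vocab <- sort(unique(unlist(tokens)))
  x <- token_matrix(tokens, vocab)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  structure(list(fit = fit, vocab = vocab, lambda = lambda, seed = seed),
            class = "baseline_classifier")
}

#' @exportS3Method base::print
print.baseline_classifier <- function(x, ...) {
  cat(sprintf("<baseline_classifier> ridge logistic regression, %d token features (lambda = %g)\n",
              length(x$vocab), x$lambda))
  invisible(x)
}

#' @rdname train_baseline_classifier
#' @param object A `baseline_classifier`.
#' @param texts Character vector of classifier inputs.
#' @param ... Unused.
#' @return `predict()`: numeric vector of probabilities in \[0, 1\].
#' @export
predict.baseline_classifier <- function(object, texts, ...) {
  x <- token_matrix(tokenize_texts(texts), object$vocab)
  as.numeric(stats::predict(object$fit, newx = x, s = object$lambda,
                            type = "response"))
}

as_scorer <- function(scorer) {
  if (inherits(scorer, "baseline_classifier")) {
    function(texts) predict(scorer, texts)
  } else if (is.function(scorer)) {
    scorer
  } else {
    abort("scorer must be a baseline_classifier or a function(texts) -> probabilities")
  }
}

#' Filter predications by relevance-classifier score
#'
#' Scores each predication's classifier text and keeps records with score at
#' or above the threshold. The scorer is pluggable: the built-in baseline,
#' any `function(texts) -> [0, 1]`, or probabilities precomputed by an
#' external model (wrap them in a lookup function).
#'
#' @param records Predication tibble.
#' @param scorer A `baseline_classifier` or a function mapping texts to
#'   probabilities in \[0, 1\].
#' @param threshold Retention threshold in \[0, 1\] (default 0.5).
#' @return A list with `retained` and `removed` tibbles, each carrying a
#'   `relevance_score` column.
#' @export
apply_relevance_filter <- function(records, scorer, threshold = 0.5) {
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    abort("threshold must be a single number in [0, 1]")
  }
  score_fn <- as_scorer(scorer)
  scores <- score_fn(build_classifier_input(records))
  if (length(scores) != nrow(records) || any(scores < 0 | scores > 1)) {
    abort("scorer must return one probability in [0, 1] per record")
  }
  records$relevance_score <- as.numeric(scores)
  keep <- records$relevance_score >= threshold
  list(retained = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Precision, recall, and F1 of binary predictions
#'
#' Confusion counts treat label 1 as the positive class. A metric whose
#' denominator is zero is reported as 0 and flagged in the `undefined`
#' attribute-style column.
#'
#' @param predicted Vector of predicted labels (0/1).
#' @param truth Vector of true labels (0/1), same length.
#' @return An object of class `classifier_metrics`: a one-row tibble with
#'   `precision`, `recall`, `f1`, `tp`, `fp`, `fn`, `tn`, `undefined`.
#' @export
evaluate_classifier <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have the same length")
  }
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (!all(predicted %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    abort("labels must be 0 or 1")
  }
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  undefined <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f1"); 0
  }
  out <- tibble(precision = precision, recall = recall, f1 = f1,
                tp = tp, fp = fp, fn = fn, tn = tn,
                undefined = paste(undefined, collapse = ","))
  class(out) <- c("classifier_metrics", class(out))
  out
}

#' @rdname evaluate_classifier
#' @param x A `classifier_metrics` object.
#' @param ... Unused.
#' @export
glance.classifier_metrics <- function(x, ...) {
  as_tibble(x)[, c("precision", "recall", "f1")]
}
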