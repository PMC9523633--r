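#' Plot the training loss trace of an embedding model
#'
#' @param object A `kge_model`.
#' @param ... Unused.
#' @return A ggplot of the mean per-example logistic loss by epoch.
#' @export
autoplot.kge_model <- function(object, ...) {
  trace <- tidy(object)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Epoch", y = "Mean logistic loss",
                  title = sprintf("%s training loss (dim %d)",
                                  object$family, object$dim)) +
    ggplot2::theme_minimal()
}

#' Plot link-prediction ranking metrics
#'
#' @param object A `ranking_metrics` object.
#' @param ... Unused.
#' @return A ggplot bar chart of MRR and Hits@k (MR is annotated in the
#'   subtitle since it lives on a different scale).
#' @export
autoplot.ranking_metrics <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$metric != "mr", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = "Link-prediction performance",
                  subtitle = sprintf("MR %.2f over %d queries (%s protocol)",
                                     object$mr, object$n_queries,
                                     object$protocol)) +
    ggplot2::theme_minimal()
}

#' Plot the composite triple-score distribution
#'
#' Histogram of the composite filtering score (normalized subject
#' out-degree + object in-degree + G-squared association) across triples,
#' with an optional retention cutoff line at the k-th best score.
#'
#' @param scored Tibble from [composite_scores()].
#' @param k Optional retention count to mark.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scored, k = NULL) {
  assert_columns(scored, "composite", "scored")
  p <- ggplot2::ggplot(scored, ggplot2::aes(x = .data$composite)) +
    ggplot2::geom_histogram(bins = 40, fill = "#756bb1") +
    ggplot2::labs(x = "Composite score", y = "Triples",
                  title = "Composite filtering score distribution") +
    ggplot2::theme_minimal()
  if (!is.null(k) && k >= 1 && k <= nrow(scored)) {
    cutoff <- sort(scored$composite, decreasing = TRUE)[k]
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot entity frequencies among top-ranked candidate triples
#'
#' @param frequencies Tibble from [frequency_rank()].
#' @param top Entities to show per relation (default 10).
#' @return A ggplot, faceted by relation.
#' @export
plot_frequency_rank <- function(frequencies, top = 10) {
  assert_columns(frequencies, c("relation", "head", "frequency"), "frequencies")
  df <- frequencies |>
    group_by(.data$relation) |>
    slice_head(n = top) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$head, .data$frequency),
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "#e6550d") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~relation, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Appearances in top-ranked lists",
                  title = "Candidate entities by top-list frequency") +
    ggplot2::theme_minimal()
}
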