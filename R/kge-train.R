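#' Train a knowledge-graph-embedding model
#'
#' From-scratch mini-batch stochastic gradient descent on the logistic loss
#' `sum log(1 + exp(-y f(h, r, t)))` over positive triples and uniformly
#' corrupted negatives (one fair coin per negative picks head- or
#' tail-corruption; the replacement entity is uniform over all entities
#' except the original). TransE entity vectors are re-normalized to unit L2
#' norm after every update step, following the original translational-model
#' recipe; DistMult and ComplEx are unconstrained. Parameters are initialized
#' uniformly on (-6/sqrt(dim), 6/sqrt(dim)). Training is deterministic given
#' `seed`.
#'
#' @param x A `knowledge_graph` from [build_graph()], or a deduplicated
#'   triple tibble with columns `head`, `relation`, `tail`.
#' @param family `"transe"`, `"distmult"`, or `"complex"`.
#' @param dim Embedding dimension (default 250, the size used for the
#'   full-corpus model; use a smaller value for small graphs).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param epochs Number of passes over the positive triples (default 200).
#' @param batch_size Mini-batch size (default 512).
#' @param negatives Corrupted triples drawn per positive (default 1).
#' @param norm_order TransE distance norm: 2 (default, L2) or 1.
#' @param filter_negatives If `TRUE`, corrupted triples that happen to be
#'   known positives are re-labeled as positives rather than negatives
#'   avoided; default `FALSE` (plain uniform corruption).
#' @param init_scale Half-width of the uniform initializer; default
#'   `6/sqrt(dim)`.
#' @param seed Integer seed controlling initialization, shuffling, and
#'   negative sampling.
#' @param verbose Print the mean loss every 25 epochs.
#' @return A `kge_model`: embedding matrices plus `loss_trace`, a tibble of
#'   the mean per-example loss at each epoch.
#' @examples
#' triples <- tibble::tibble(
#'   head = c("a", "b", "c"), relation = "R", tail = c("b", "c", "a")
#' )
#' m <- kge_train(triples, "transe", dim = 4, epochs = 5, seed = 1)
#' kge_score(m, "a", "R", "b")
#' @export
kge_train <- function(x, family = kge_families, dim = 250,
                      learning_rate = 0.01, epochs = 200, batch_size = 512,
                      negatives = 1, norm_order = 2, filter_negatives = FALSE,
                      init_scale = NULL, seed = 1, verbose = FALSE) {
  family <- match.arg(family)
  graph <- if (inherits(x, "knowledge_graph")) x else build_graph(x)
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (epochs < 1) abort("epochs must be at least 1")
  if (negatives < 1) abort("negatives must be at least 1")
  if (dim < 1) abort("dim must be at least 1")
  if (!norm_order %in% c(1, 2)) abort("norm_order must be 1 or 2")
  n_pos <- nrow(graph$triples)
  n_ent <- length(graph$entities)
  if (n_pos < 1) abort("cannot train on an empty graph")
  if (n_ent < 2) abort("need at least 2 entities to train")

  set.seed(seed)
  params <- init_kge_params(family, n_ent, length(graph$relations), dim, init_scale)
  model <- new_kge_model(
    family, graph$entities, graph$relations, dim, norm_order, params,
    config = list(dim = dim, learning_rate = learning_rate, epochs = epochs,
                  batch_size = batch_size, negatives = negatives,
                  norm_order = norm_order, filter_negatives = filter_negatives,
                  init_scale = init_scale %||% (6 / sqrt(dim)), seed = seed)
  )
  H <- graph$triples$head_id
  R <- graph$triples$relation_id
  Tl <- graph$triples$tail_id
  known <- if (filter_negatives) triple_key(H, R, Tl) else NULL

  apply_update <- function(slot, idx, grad) {
    agg <- rowsum(grad, idx)
    uix <- as.integer(rownames(agg))
    model[[slot]][uix, ] <<- model[[slot]][uix, , drop = FALSE] -
      learning_rate * agg
    uix
  }

  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n_pos)
    ep_loss <- 0
    ep_n <- 0L
    for (start in seq(1, n_pos, by = batch_size)) {
      b <- perm[start:min(start + batch_size - 1, n_pos)]
      neg <- corrupt_triples(H[b], R[b], Tl[b], n_ent, negatives)
      y <- c(rep(1, length(b)), rep(-1, length(neg$h)))
      if (filter_negatives) {
        acc_true <- triple_key(neg$h, neg$r, neg$t) %in% known
        y[length(b) + which(acc_true)] <- 1
      }
      bh <- c(H[b], neg$h); br <- c(R[b], neg$r); bt <- c(Tl[b], neg$t)
      g <- kge_grad_batch(model, bh, br, bt, y)
      ep_loss <- ep_loss + g$loss
      ep_n <- ep_n + length(y)
      if (family == "complex") {
        touched <- apply_update("ent_re", g$ent_re_idx, g$ent_re_grad)
        apply_update("ent_im", g$ent_im_idx, g$ent_im_grad)
        apply_update("rel_re", g$rel_re_idx, g$rel_re_grad)
        apply_update("rel_im", g$rel_im_idx, g$rel_im_grad)
      } else {
        touched <- apply_update("ent", g$ent_idx, g$ent_grad)
        apply_update("rel", g$rel_idx, g$rel_grad)
        if (family == "transe") {
          model$ent <- normalize_rows(model$ent, touched)
        }
      }
    }
    loss_trace[ep] <- ep_loss / ep_n
    if (verbose && (ep %% 25 == 0 || ep == 1)) {
      inform(sprintf("epoch %d: mean loss %.4f", ep, loss_trace[ep]))
    }
  }
  model$loss_trace <- tibble(epoch = seq_len(epochs), loss = loss_trace)
  model
}

#' @rdname kge_train
#' @param object,x A `kge_model`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch loss trace; `glance()`: a one-row model
#'   summary.
#' @export
tidy.kge_model <- function(x, ...) {
  x$loss_trace %||% tibble(epoch = integer(), loss = numeric())
}

#' @rdname kge_train
#' @export
glance.kge_model <- function(x, ...) {
  tibble(
    family = x$family, dim = x$dim,
    n_entities = length(x$entities), n_relations = length(x$relations),
    epochs = if (is.null(x$loss_trace)) 0L else nrow(x$loss_trace),
    final_loss = if (is.null(x$loss_trace) || nrow(x$loss_trace) == 0)
      NA_real_ else x$loss_trace$loss[nrow(x$loss_trace)]
  )
}

#' Save or load a trained embedding model as plain text
#'
#' The checkpoint is a directory holding the embedding matrices as CSV files
#' plus a JSON sidecar with the family, dimension, index labels, and training
#' configuration.
#'
#' @param model A `kge_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `write_kge_model()` returns `dir` invisibly; `read_kge_model()`
#'   returns the restored `kge_model`.
#' @export
write_kge_model <- function(model, dir) {
  stopifnot(inherits(model, "kge_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slots <- if (model$family == "complex")
    c("ent_re", "ent_im", "rel_re", "rel_im") else c("ent", "rel")
  for (s in slots) {
    readr::write_csv(as.data.frame(model[[s]]), file.path(dir, paste0(s, ".csv")),
                     progress = FALSE)
  }
  meta <- list(family = model$family, dim = model$dim,
               norm_order = model$norm_order, entities = model$entities,
               relations = model$relations, config = model$config,
               loss_trace = model$loss_trace)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_kge_model
#' @export
read_kge_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  slots <- if (meta$family == "complex")
    c("ent_re", "ent_im", "rel_re", "rel_im") else c("ent", "rel")
  params <- lapply(slots, function(s) {
    as.matrix(readr::read_csv(file.path(dir, paste0(s, ".csv")),
                              col_types = readr::cols(.default = "d"),
                              progress = FALSE))
  })
  names(params) <- slots
  params <- lapply(params, function(m) {
    dimnames(m) <- NULL
    m
  })
  model <- new_kge_model(meta$family, meta$entities, meta$relations,
                         as.integer(meta$dim), as.integer(meta$norm_order),
                         params, config = meta$config)
  if (!is.null(meta$loss_trace)) model$loss_trace <- as_tibble(meta$loss_trace)
  model
}
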