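# Knowledge-graph-embedding scoring functions and their analytic gradients.
#
# Families:
#   transe   f(h,r,t) = -|| h + r - t ||_p          (translational, p in {1,2})
#   distmult f(h,r,t) = sum_i h_i r_i t_i           (diagonal bilinear, symmetric)
#   complex  f(h,r,t) = Re( sum_i h_i r_i conj(t_i)) (complex bilinear, asymmetric)
#
# Internally every family stores real matrices; ComplEx keeps separate real
# and imaginary parts for entities and relations.

kge_families <- c("transe", "distmult", "complex")

new_kge_model <- function(family, entities, relations, dim, norm_order,
                          params, loss_trace = NULL, config = list()) {
  structure(
    c(list(family = family, entities = entities, relations = relations,
           dim = dim, norm_order = norm_order, loss_trace = loss_trace,
           config = config),
      params),
    class = "kge_model"
  )
}

#' @exportS3Method base::print
print.kge_model <- function(x, ...) {
  cat(sprintf("<kge_model> %s | dim %d | %d entities | %d relations%s\n",
              x$family, x$dim, length(x$entities), length(x$relations),
              if (x$family == "transe") sprintf(" | L%d distance", x$norm_order) else ""))
  if (!is.null(x$loss_trace) && nrow(x$loss_trace) > 0) {
    cat(sprintf("  trained %d epochs; final mean loss %.4f\n",
                max(x$loss_trace$epoch), x$loss_trace$loss[nrow(x$loss_trace)]))
  }
  invisible(x)
}

init_kge_params <- function(family, n_ent, n_rel, dim, init_scale = NULL) {
  b <- init_scale %||% (6 / sqrt(dim))
  rmat <- function(n) matrix(runif(n * dim, -b, b), nrow = n, ncol = dim)
  if (family == "complex") {
    list(ent_re = rmat(n_ent), ent_im = rmat(n_ent),
         rel_re = rmat(n_rel), rel_im = rmat(n_rel))
  } else {
    params <- list(ent = rmat(n_ent), rel = rmat(n_rel))
    if (family == "transe") params$ent <- normalize_rows(params$ent)
    params
  }
}

normalize_rows <- function(m, rows = seq_len(nrow(m))) {
  nrm <- sqrt(rowSums(m[rows, , drop = FALSE]^2))
  nrm[nrm == 0] <- 1
  m[rows, ] <- m[rows, , drop = FALSE] / nrm
  m
}

# Vectorized scoring over aligned integer index vectors. Products are grouped
# so the head/tail-swap identities (DistMult symmetry, ComplEx antisymmetry
# under purely imaginary relations) hold bitwise in floating point: the two
# entity factors are always combined first.
kge_score_idx <- function(model, h, r, t) {
  switch(model$family,
    transe = {
      diff <- model$ent[h, , drop = FALSE] + model$rel[r, , drop = FALSE] -
        model$ent[t, , drop = FALSE]
      if (model$norm_order == 2) -sqrt(rowSums(diff^2)) else -rowSums(abs(diff))
    },
    distmult = rowSums((model$ent[h, , drop = FALSE] *
                          model$ent[t, , drop = FALSE]) *
                         model$rel[r, , drop = FALSE]),
    complex = {
      a <- model$ent_re[h, , drop = FALSE]; b <- model$ent_im[h, , drop = FALSE]
      cc <- model$rel_re[r, , drop = FALSE]; dd <- model$rel_im[r, , drop = FALSE]
      e <- model$ent_re[t, , drop = FALSE]; g <- model$ent_im[t, , drop = FALSE]
      # Re(h r conj(t)) = r_re (h_re t_re + h_im t_im) + r_im (h_re t_im - h_im t_re)
      rowSums(cc * (a * e + b * g) + dd * (a * g - b * e))
    }
  )
}

# Score every entity substituted on one side of a query; returns a length-n
# vector. Shares kge_score_idx so ranking sees the identical float path as
# single-triple scoring.
kge_score_all <- function(model, side, h, r, t) {
  n <- length(model$entities)
  cand <- seq_len(n)
  if (side == "tail") {
    kge_score_idx(model, rep.int(h, n), rep.int(r, n), cand)
  } else {
    kge_score_idx(model, cand, rep.int(r, n), rep.int(t, n))
  }
}

resolve_entities <- function(model, x, what = "entity") {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1 | x > length(model$entities))) abort(sprintf("%s index out of range", what))
    return(x)
  }
  idx <- match(x, model$entities)
  if (anyNA(idx)) {
    abort(sprintf("unknown %s: %s", what,
                  paste(head(unique(x[is.na(idx)]), 5), collapse = ", ")))
  }
  idx
}

resolve_relations <- function(model, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1 | x > length(model$relations))) abort("relation index out of range")
    return(x)
  }
  idx <- match(x, model$relations)
  if (anyNA(idx)) {
    abort(sprintf("unknown relation: %s",
                  paste(head(unique(x[is.na(idx)]), 5), collapse = ", ")))
  }
  idx
}

#' Score triples under a trained embedding model
#'
#' Evaluates the model family's scoring function: `-||h + r - t||_p` for
#' TransE, `sum_i h_i r_i t_i` for DistMult, and
#' `Re(sum_i h_i r_i conj(t_i))` for ComplEx. Higher scores mean the model
#' considers the triple more plausible.
#'
#' @param model A `kge_model` from [kge_train()].
#' @param head,relation,tail Entity / relation labels (or integer indices),
#'   recycled to a common length.
#' @return Numeric vector of scores.
#' @export
kge_score <- function(model, head, relation, tail) {
  stopifnot(inherits(model, "kge_model"))
  n <- max(length(head), length(relation), length(tail))
  h <- resolve_entities(model, rep_len(head, n), "head entity")
  r <- resolve_relations(model, rep_len(relation, n))
  t <- resolve_entities(model, rep_len(tail, n), "tail entity")
  kge_score_idx(model, h, r, t)
}

#' Corrupt triples for negative sampling
#'
#' For each positive triple and each of `k` draws, a fair coin chooses
#' whether to corrupt the head or the tail; the corrupted slot is replaced
#' by an entity drawn uniformly from all entities except the original, and
#' the relation is left unchanged. Uses the current RNG state.
#'
#' @param h,r,t Aligned integer index vectors of the positive triples.
#' @param n_entities Number of entities to draw replacements from (>= 2).
#' @param k Negatives per positive.
#' @return A list with integer vectors `h`, `r`, `t` of length
#'   `length(h) * k` and `source` (index of the originating positive).
#' @export
corrupt_triples <- function(h, r, t, n_entities, k = 1) {
  if (n_entities < 2) abort("need at least 2 entities to corrupt triples")
  m <- length(h)
  total <- m * k
  src <- rep(seq_len(m), times = k)
  corrupt_head <- runif(total) < 0.5
  orig <- ifelse(corrupt_head, h[src], t[src])
  repl <- sample.int(n_entities - 1L, total, replace = TRUE)
  repl <- repl + (repl >= orig)
  nh <- ifelse(corrupt_head, repl, h[src])
  nt <- ifelse(corrupt_head, t[src], repl)
  list(h = as.integer(nh), r = r[src], t = as.integer(nt), source = src,
       corrupt_head = corrupt_head)
}

#' Logistic loss over scored triples
#'
#' `sum_i log(1 + exp(-y_i * f_i))` with labels y = +1 for positive and
#' -1 for corrupted triples, evaluated with a numerically stable softplus.
#'
#' @param scores Numeric vector of model scores f(h, r, t).
#' @param labels Vector of +1 / -1 labels, same length.
#' @return A single non-negative number.
#' @export
logistic_loss <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores and labels must align")
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1 or -1")
  sum(softplus(-labels * scores))
}

# Per-example gradients of the logistic loss w.r.t. the embedding rows used
# by a batch. Returns scatter-ready index vectors + gradient row matrices.
kge_grad_batch <- function(model, h, r, t, y) {
  f <- kge_score_idx(model, h, r, t)
  gf <- -y * plogis(-y * f)   # dL/df per example
  if (model$family == "transe") {
    diff <- model$ent[h, , drop = FALSE] + model$rel[r, , drop = FALSE] -
      model$ent[t, , drop = FALSE]
    if (model$norm_order == 2) {
      dist <- sqrt(rowSums(diff^2))
      dist[dist == 0] <- 1
      u <- diff / dist
    } else {
      u <- sign(diff)
    }
    gu <- gf * u   # df/dh = -u, df/dr = -u, df/dt = +u
    list(loss = sum(softplus(-y * f)),
         ent_idx = c(h, t), ent_grad = rbind(-gu, gu),
         rel_idx = r, rel_grad = -gu)
  } else if (model$family == "distmult") {
    he <- model$ent[h, , drop = FALSE]
    re <- model$rel[r, , drop = FALSE]
    te <- model$ent[t, , drop = FALSE]
    list(loss = sum(softplus(-y * f)),
         ent_idx = c(h, t), ent_grad = rbind(gf * (re * te), gf * (he * re)),
         rel_idx = r, rel_grad = gf * (he * te))
  } else {
    a <- model$ent_re[h, , drop = FALSE]; b <- model$ent_im[h, , drop = FALSE]
    cc <- model$rel_re[r, , drop = FALSE]; dd <- model$rel_im[r, , drop = FALSE]
    e <- model$ent_re[t, , drop = FALSE]; g <- model$ent_im[t, , drop = FALSE]
    list(loss = sum(softplus(-y * f)),
         ent_re_idx = c(h, t),
         ent_re_grad = rbind(gf * (cc * e + dd * g), gf * (a * cc - b * dd)),
         ent_im_idx = c(h, t),
         ent_im_grad = rbind(gf * (cc * g - dd * e), gf * (a * dd + b * cc)),
         rel_re_idx = r, rel_re_grad = gf * (a * e + b * g),
         rel_im_idx = r, rel_im_grad = gf * (a * g - b * e))
  }
}

# Accumulate per-example gradient rows into a full parameter-shaped matrix.
scatter_full <- function(shape_mat, idx, grad) {
  out <- matrix(0, nrow = nrow(shape_mat), ncol = ncol(shape_mat))
  agg <- rowsum(grad, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Verify analytic gradients against central finite differences
#'
#' Builds a small random model and batch, computes the analytic gradient of
#' the total logistic loss with respect to every embedding parameter, and
#' compares it against central finite differences (step 1e-5).
#'
#' @param family `"transe"`, `"distmult"`, or `"complex"`.
#' @param dim Embedding dimension (small; default 8).
#' @param seed Integer seed.
#' @param norm_order TransE distance norm, 1 or 2.
#' @return The maximum relative gradient error (a small number when the
#'   analytic gradients are correct).
#' @export
gradient_check <- function(family = kge_families, dim = 8, seed = 1,
                           norm_order = 2) {
  family <- match.arg(family)
  if (dim > 8) abort("gradient_check is meant for dim <= 8")
  set.seed(seed)
  n_ent <- 5L; n_rel <- 3L; m <- 8L
  params <- init_kge_params(family, n_ent, n_rel, dim, init_scale = 1)
  model <- new_kge_model(family, paste0("E", 1:n_ent), paste0("R", 1:n_rel),
                         dim, norm_order, params)
  h <- sample.int(n_ent, m, replace = TRUE)
  r <- sample.int(n_rel, m, replace = TRUE)
  t <- sample.int(n_ent, m, replace = TRUE)
  y <- sample(c(-1, 1), m, replace = TRUE)

  slots <- if (family == "complex") {
    c("ent_re", "ent_im", "rel_re", "rel_im")
  } else {
    c("ent", "rel")
  }
  g <- kge_grad_batch(model, h, r, t, y)
  analytic <- lapply(slots, function(s) {
    base <- if (startsWith(s, "ent")) "ent" else "rel"
    key <- if (family == "complex") s else base
    scatter_full(model[[s]], g[[paste0(key, "_idx")]], g[[paste0(key, "_grad")]])
  })
  names(analytic) <- slots

  loss_at <- function(mod) logistic_loss(kge_score_idx(mod, h, r, t), y)
  eps <- 1e-5
  max_err <- 0
  for (s in slots) {
    M <- model[[s]]
    for (i in seq_len(nrow(M))) {
      for (j in seq_len(ncol(M))) {
        mp <- model; mp[[s]][i, j] <- M[i, j] + eps
        mm <- model; mm[[s]][i, j] <- M[i, j] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        ana <- analytic[[s]][i, j]
        err <- abs(num - ana) / max(abs(num), abs(ana), 1e-8)
        if (err > max_err) max_err <- err
      }
    }
  }
  max_err
}
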