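# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed by the callers.

random_predications <- function(n, n_entities = 12, n_relations = 3,
                                seed = NULL, p_missing_year = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("C%07d", seq_len(n_entities))
  sem_pool <- c("dsyn", "phsu", "orch", "gngm", "cnce", "idcn", "acty")
  sem <- sample(sem_pool, n_entities, replace = TRUE)
  rel <- c("TREATS", "PREVENTS", "AFFECTS")[seq_len(n_relations)]
  si <- sample.int(n_entities, n, replace = TRUE)
  oi <- sample.int(n_entities, n, replace = TRUE)
  tibble::tibble(
    subject_id = ids[si],
    subject_name = paste("name", si),
    subject_semtype = sem[si],
    predicate = sample(rel, n, replace = TRUE),
    object_id = ids[oi],
    object_name = paste("name", oi),
    object_semtype = sem[oi],
    pmid = sprintf("%07d", sample.int(9999999L, n, replace = TRUE)),
    year = ifelse(stats::runif(n) < p_missing_year, NA_integer_,
                  sample(2000:2022, n, replace = TRUE)),
    sentence = paste("observed link between", ids[si], "and", ids[oi])
  )
}

# A model with random parameters, built without training.
random_kge_model <- function(family, n_ent = 5, n_rel = 2, dim = 4, seed = 1,
                             norm_order = 2) {
  set.seed(seed)
  params <- kgmine:::init_kge_params(family, n_ent, n_rel, dim, init_scale = 1)
  kgmine:::new_kge_model(family, sprintf("E%02d", seq_len(n_ent)),
                         sprintf("R%d", seq_len(n_rel)), dim, norm_order, params)
}

# Naive per-coordinate loop scorer, independent of the vectorized code path.
naive_score <- function(model, h, r, t) {
  d <- model$dim
  if (model$family == "transe") {
    s <- 0
    for (i in seq_len(d)) {
      di <- model$ent[h, i] + model$rel[r, i] - model$ent[t, i]
      s <- s + (if (model$norm_order == 2) di^2 else abs(di))
    }
    if (model$norm_order == 2) -sqrt(s) else -s
  } else if (model$family == "distmult") {
    s <- 0
    for (i in seq_len(d)) s <- s + model$ent[h, i] * model$rel[r, i] * model$ent[t, i]
    s
  } else {
    s <- 0
    for (i in seq_len(d)) {
      hc <- complex(real = model$ent_re[h, i], imaginary = model$ent_im[h, i])
      rc <- complex(real = model$rel_re[r, i], imaginary = model$rel_im[r, i])
      tc <- complex(real = model$ent_re[t, i], imaginary = model$ent_im[t, i])
      s <- s + Re(hc * rc * Conj(tc))
    }
    s
  }
}

# Exhaustive rank oracle: score every candidate one by one via kge_score and
# apply the mean-rank tie policy directly.
oracle_rank <- function(model, head, relation, tail, side, protocol = "raw",
                        known = NULL) {
  ents <- model$entities
  scores <- vapply(ents, function(e) {
    if (side == "tail") kge_score(model, head, relation, e)
    else kge_score(model, e, relation, tail)
  }, numeric(1))
  true_ent <- if (side == "tail") tail else head
  keep <- rep(TRUE, length(ents))
  if (protocol == "filtered" && !is.null(known) && nrow(known) > 0) {
    kk <- paste(known$head, known$relation, known$tail)
    qk <- if (side == "tail") paste(head, relation, ents) else
      paste(ents, relation, tail)
    keep <- !(qk %in% kk)
    keep[ents == true_ent] <- TRUE
  }
  st <- scores[ents == true_ent]
  s <- scores[keep]
  1 + sum(s > st) + (sum(s == st) - 1) / 2
}

triple_set <- function(df) sort(paste(df$head, df$relation, df$tail))
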