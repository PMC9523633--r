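#' Configuration for the synthetic predication-corpus generator
#'
#' The generator emulates a literature-derived predication corpus at a scale
#' where the full pipeline runs in minutes on one CPU: entities live at
#' latent positions in a low-dimensional space, each relation is a latent
#' translation, and a triple is *rule-true* when the translated head lands
#' within `tau` of the tail. Rule-true triples are emitted as predications
#' (duplicated across 1--3 synthetic citations), diluted with uniformly
#' random false triples, and stamped with publication years straddling the
#' time-slice boundary. A held-out fraction of rule-true triples and a set
#' of planted repurposing pairs (category-head, TREATS, disease-tail) are
#' withheld from the corpus so that recovery can be measured.
#'
#' @param n_entities Number of entities (>= 10; default 300).
#' @param n_relations Number of relations (default 4: TREATS, PREVENTS,
#'   AFFECTS, INTERACTS_WITH).
#' @param latent_dim Latent space dimension (default 8).
#' @param tau Rule-truth threshold. For the translational rule this is the
#'   Euclidean distance below which a triple is true (default 1.9, giving
#'   roughly 3,000 true triples at the default scale); for the bilinear rule
#'   it is the score above which a triple is true (default 8).
#' @param rule `"translational"` (default; matched to TransE) or
#'   `"bilinear"` (matched to DistMult/ComplEx).
#' @param rel_scale Standard deviation of the latent relation translation
#'   vectors under the translational rule (default 0.5); the bilinear rule
#'   uses unit-scale relation weight vectors.
#' @param noise_rate False (non-rule-true) predications emitted per true
#'   triple, in \[0, 1) (default 0.05).
#' @param holdout_fraction Fraction of rule-true triples withheld from the
#'   corpus for link-prediction evaluation (default 0.10).
#' @param plant_fraction Fraction of (category-head, TREATS, disease-tail)
#'   rule-true triples withheld as planted repurposing pairs (default 0.5).
#' @param n_ad_tails Number of disease-like tail concepts (default 10).
#' @param n_category_heads Size of the drug-like candidate category,
#'   including decoy heads with no TREATS edge to any disease tail
#'   (default 40).
#' @param fraction_blocked Fraction of entities assigned semantic types from
#'   generic (blocklisted) groups (default 0.1).
#' @param year_range Publication-year span (default 2000--2022).
#' @param train_before,valid_through Time-slice boundary years the year
#'   mixture is built around (defaults 2019 / 2020; about 60% of triples
#'   fall before the boundary, 22% in the validation years, 18% after).
#' @param annotation_noise Label-flip probability for
#'   [generate_annotations()] (default 0.1; must be < 0.5).
#' @param seed Integer seed; the whole corpus is deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_entities = 300, n_relations = 4,
                             latent_dim = 8, tau = NULL,
                             rule = c("translational", "bilinear"),
                             rel_scale = 0.5, noise_rate = 0.05,
                             holdout_fraction = 0.10, plant_fraction = 0.5,
                             n_ad_tails = 10, n_category_heads = 40,
                             fraction_blocked = 0.1,
                             year_range = c(2000, 2022),
                             train_before = 2019, valid_through = 2020,
                             annotation_noise = 0.1, seed = 42) {
  rule <- match.arg(rule)
  if (n_entities < 10) abort("n_entities must be at least 10")
  if (noise_rate < 0 || noise_rate >= 1) abort("noise_rate must be in [0, 1)")
  if (annotation_noise < 0 || annotation_noise >= 0.5) {
    abort("annotation_noise must be in [0, 0.5)")
  }
  tau <- tau %||% (if (rule == "translational") 1.85 else 8)
  if (tau <= 0) abort("tau must be positive")
  structure(
    list(n_entities = n_entities, n_relations = n_relations,
         latent_dim = latent_dim, tau = tau, rule = rule,
         rel_scale = rel_scale, noise_rate = noise_rate,
         holdout_fraction = holdout_fraction, plant_fraction = plant_fraction,
         n_ad_tails = n_ad_tails, n_category_heads = n_category_heads,
         fraction_blocked = fraction_blocked, year_range = year_range,
         train_before = train_before, valid_through = valid_through,
         annotation_noise = annotation_noise, seed = seed),
    class = "synthetic_config"
  )
}

synthetic_relations <- function(n) {
  base <- c("TREATS", "PREVENTS", "AFFECTS", "INTERACTS_WITH", "STIMULATES",
            "INHIBITS", "DISRUPTS", "AUGMENTS", "CAUSES", "PREDISPOSES")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("REL_", seq_len(n - length(base))))
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

blocked_semtypes <- c("cnce", "idcn", "acty", "phob", "ocdi", "orgt", "eehu")
kept_semtypes <- c("orch", "aapp", "gngm", "bpoc", "celf", "bact", "sosy", "topp")

# All rule-true (head, relation, tail) index triples under the latent rule.
rule_true_triples <- function(X, V, tau, rule) {
  n <- nrow(X)
  out <- vector("list", nrow(V))
  xsq <- rowSums(X^2)
  for (ri in seq_len(nrow(V))) {
    if (rule == "translational") {
      A <- sweep(X, 2, V[ri, ], `+`)
      d2 <- outer(rowSums(A^2), xsq, `+`) - 2 * (A %*% t(X))
      hit <- which(d2 < tau^2, arr.ind = TRUE)
    } else {
      S <- (sweep(X, 2, V[ri, ], `*`)) %*% t(X)
      hit <- which(S > tau, arr.ind = TRUE)
    }
    hit <- hit[hit[, 1] != hit[, 2], , drop = FALSE]
    out[[ri]] <- tibble(head_id = as.integer(hit[, 1]),
                        relation_id = ri,
                        tail_id = as.integer(hit[, 2]))
  }
  bind_rows(out)
}

#' Generate a synthetic predication corpus with planted structure
#'
#' See [synthetic_config()] for the generative model. The returned truth
#' object records everything a test needs: the latent geometry, the full
#' rule-true triple set, the held-out and planted subsets (absent from the
#' emitted predications), the disease-tail whitelist, and the candidate
#' category with its decoy heads.
#'
#' @param config A `synthetic_config`.
#' @return A list with `predications` (a tibble in the package's predication
#'   layout) and `truth` (a list; see Details).
#' @export
generate_kg <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_entities
  entities <- sprintf("C%07d", seq_len(n))
  entity_names <- sprintf("concept %04d", seq_len(n))
  relations <- synthetic_relations(config$n_relations)

  X <- matrix(rnorm(n * config$latent_dim), nrow = n)
  v_scale <- if (config$rule == "translational") config$rel_scale else 1
  V <- matrix(rnorm(config$n_relations * config$latent_dim, sd = v_scale),
              nrow = config$n_relations)

  true <- rule_true_triples(X, V, config$tau, config$rule)
  if (nrow(true) == 0) {
    abort("tau yields zero rule-true triples; increase tau (translational) or lower it (bilinear)")
  }

  semtypes <- ifelse(runif(n) < config$fraction_blocked,
                     sample(blocked_semtypes, n, replace = TRUE),
                     sample(kept_semtypes, n, replace = TRUE))

  # Disease-like tails: most-treated entities under the TREATS relation.
  treats <- true[true$relation_id == 1, , drop = FALSE]
  tail_counts <- sort(table(treats$tail_id), decreasing = TRUE)
  ad_tail_ids <- as.integer(names(tail_counts))[seq_len(min(config$n_ad_tails,
                                                            length(tail_counts)))]
  if (length(ad_tail_ids) == 0) abort("no TREATS edges; cannot place disease tails")
  semtypes[ad_tail_ids] <- "dsyn"

  # Candidate heads: entities with a TREATS edge into a disease tail, plus an
  # equal-sized share of decoys that have none (so rank comparisons between
  # planted and decoy heads are balanced).
  true_head_ids <- sort(setdiff(unique(treats$head_id[treats$tail_id %in% ad_tail_ids]),
                                ad_tail_ids))
  n_true_keep <- min(length(true_head_ids), ceiling(config$n_category_heads / 2))
  true_head_ids <- sort(resample(true_head_ids, n_true_keep))
  pool <- setdiff(seq_len(n), c(ad_tail_ids, unique(treats$head_id)))
  n_decoys <- max(config$n_category_heads - n_true_keep, 0)
  decoy_ids <- sort(resample(pool, min(n_decoys, length(pool))))
  head_ids <- c(true_head_ids, decoy_ids)
  semtypes[head_ids] <- "phsu"

  # Planted repurposing pairs: withheld (head, TREATS, tail) rule-true triples.
  plantable <- which(true$relation_id == 1 & true$head_id %in% true_head_ids &
                       true$tail_id %in% ad_tail_ids)
  n_plant <- ceiling(config$plant_fraction * length(plantable))
  planted_idx <- sort(resample(plantable, n_plant))

  remaining <- setdiff(seq_len(nrow(true)), planted_idx)
  n_hold <- round(config$holdout_fraction * length(remaining))
  holdout_idx <- sort(resample(remaining, n_hold))
  emit_idx <- setdiff(remaining, holdout_idx)

  emitted <- true[emit_idx, , drop = FALSE]

  # Noise: uniformly random false triples, distinct from every rule-true one.
  n_noise <- round(config$noise_rate * nrow(emitted))
  true_keys <- triple_key(true$head_id, true$relation_id, true$tail_id)
  noise <- tibble(head_id = integer(), relation_id = integer(), tail_id = integer())
  while (nrow(noise) < n_noise) {
    m <- (n_noise - nrow(noise)) * 2 + 10
    cand <- tibble(head_id = sample.int(n, m, replace = TRUE),
                   relation_id = sample.int(config$n_relations, m, replace = TRUE),
                   tail_id = sample.int(n, m, replace = TRUE))
    cand <- cand[cand$head_id != cand$tail_id &
                   !(triple_key(cand$head_id, cand$relation_id, cand$tail_id)
                     %in% true_keys), , drop = FALSE]
    noise <- distinct(bind_rows(noise, cand))
  }
  noise <- noise[seq_len(n_noise), , drop = FALSE]

  triples <- bind_rows(mutate(emitted, rule_true = TRUE),
                       mutate(noise, rule_true = FALSE))

  # Publication years: a mixture placing ~60% of triples before the training
  # boundary, ~22% in the validation years, ~18% after.
  yr <- config$year_range
  slot <- sample(c("train", "valid", "test"), nrow(triples), replace = TRUE,
                 prob = c(0.60, 0.22, 0.18))
  primary_year <- integer(nrow(triples))
  primary_year[slot == "train"] <- resample(seq(yr[1], config$train_before - 1),
                                            sum(slot == "train"), replace = TRUE)
  primary_year[slot == "valid"] <- resample(seq(config$train_before, config$valid_through),
                                            sum(slot == "valid"), replace = TRUE)
  primary_year[slot == "test"] <- resample(seq(config$valid_through + 1, yr[2]),
                                           sum(slot == "test"), replace = TRUE)

  n_mentions <- sample(1:3, nrow(triples), replace = TRUE)
  rows <- rep(seq_len(nrow(triples)), n_mentions)
  first <- !duplicated(rows)
  year <- primary_year[rows] + ifelse(first, 0L, sample(0:2, length(rows), replace = TRUE))
  year <- pmin(year, yr[2])

  preds <- tibble(
    subject_id = entities[triples$head_id[rows]],
    subject_name = entity_names[triples$head_id[rows]],
    subject_semtype = semtypes[triples$head_id[rows]],
    predicate = relations[triples$relation_id[rows]],
    object_id = entities[triples$tail_id[rows]],
    object_name = entity_names[triples$tail_id[rows]],
    object_semtype = semtypes[triples$tail_id[rows]],
    pmid = sprintf("%08d", sample.int(99999999L, length(rows))),
    year = as.integer(year),
    sentence = paste(entity_names[triples$head_id[rows]],
                     tolower(relations[triples$relation_id[rows]]),
                     entity_names[triples$tail_id[rows]],
                     "in a synthetic corpus record")
  )
  preds <- preds[sample.int(nrow(preds)), , drop = FALSE]

  as_labels <- function(idx_tbl) {
    tibble(head = entities[idx_tbl$head_id],
           relation = relations[idx_tbl$relation_id],
           tail = entities[idx_tbl$tail_id])
  }

  truth <- list(
    latent = X, relation_vectors = V,
    entities = entities, relations = relations, semtypes = semtypes,
    rule_true = as_labels(true),
    held_out = as_labels(true[holdout_idx, , drop = FALSE]),
    planted = as_labels(true[planted_idx, , drop = FALSE]),
    noise = as_labels(noise),
    ad_tails = entities[ad_tail_ids],
    category_heads = entities[head_ids],
    true_heads = entities[true_head_ids],
    decoy_heads = entities[decoy_ids],
    config = config
  )
  list(predications = preds, truth = truth)
}

annotation_vocab <- list(
  true = c("inhibits", "ameliorates", "attenuates", "improves", "restores",
           "protects", "reduces", "rescues", "benefit", "efficacy"),
  false = c("unrelated", "spurious", "coincidental", "artifact", "confounded",
            "ambiguous", "unclear", "incidental", "noise", "unsupported"),
  shared = c("patients", "study", "cohort", "model", "observed", "analysis",
             "results", "trial")
)

#' Generate noisy binary triple annotations
#'
#' Emulates a manually annotated triple-correctness set: each predication is
#' labeled 1 if its triple is rule-true and 0 if it is noise, with each label
#' flipped independently with probability `annotation_noise`. The classifier
#' text is built with [build_classifier_input()] from a synthetic sentence
#' whose vocabulary correlates with the true (pre-flip) label, so the
#' annotations are learnable.
#'
#' @param predications Predication tibble from [generate_kg()].
#' @param truth Truth object from [generate_kg()].
#' @param annotation_noise Flip probability in \[0, 0.5); defaults to the
#'   generator config's value.
#' @param seed Integer seed.
#' @param balance If `TRUE` (default), downsample the majority class so that
#'   correct and incorrect triples are equally represented, the way manual
#'   annotation sets are usually constructed; `FALSE` labels every
#'   predication.
#' @return A tibble with columns `text`, `label` (possibly flipped), and
#'   `truth_label` (the rule-truth membership).
#' @export
generate_annotations <- function(predications, truth,
                                 annotation_noise = NULL, seed = 1,
                                 balance = TRUE) {
  annotation_noise <- annotation_noise %||% truth$config$annotation_noise
  if (annotation_noise < 0 || annotation_noise >= 0.5) {
    abort("annotation_noise must be in [0, 0.5)")
  }
  set.seed(seed)
  keys <- triple_key(predications$subject_id, predications$predicate,
                     predications$object_id)
  true_keys <- triple_key(truth$rule_true$head, truth$rule_true$relation,
                          truth$rule_true$tail)
  member <- keys %in% true_keys
  if (balance && length(unique(member)) == 2) {
    n_min <- min(sum(member), sum(!member))
    keep <- sort(c(resample(which(member), n_min),
                   resample(which(!member), n_min)))
    predications <- predications[keep, , drop = FALSE]
    member <- member[keep]
  }
  m <- nrow(predications)
  pick <- function(vocab, k) {
    vapply(seq_len(k), function(i) paste(sample(vocab, 3), collapse = " "),
           character(1))
  }
  signal <- character(m)
  signal[member] <- pick(annotation_vocab$true, sum(member))
  signal[!member] <- pick(annotation_vocab$false, sum(!member))
  filler <- pick(annotation_vocab$shared, m)
  recs <- predications
  recs$sentence <- paste(signal, filler)
  flip <- runif(m) < annotation_noise
  tibble(
    text = build_classifier_input(recs),
    label = as.integer(xor(member, flip)),
    truth_label = as.integer(member)
  )
}

#' Summarise a predication corpus
#'
#' Stage-count reporting: number of predication mentions, distinct triples,
#' entities, relations, and the per-year mention histogram.
#'
#' @param predications Predication tibble.
#' @return A list of class `corpus_summary` with fields `n_predications`,
#'   `n_triples`, `n_entities`, `n_relations`, `years` (tibble).
#' @export
corpus_summary <- function(predications) {
  if (nrow(predications) == 0) {
    out <- list(n_predications = 0L, n_triples = 0L, n_entities = 0L,
                n_relations = 0L, years = tibble(year = integer(), n = integer()))
    return(structure(out, class = "corpus_summary"))
  }
  keys <- triple_key(predications$subject_id, predications$predicate,
                     predications$object_id)
  years <- predications |>
    count(.data$year) |>
    arrange(.data$year)
  structure(
    list(
      n_predications = nrow(predications),
      n_triples = length(unique(keys)),
      n_entities = length(unique(c(predications$subject_id,
                                   predications$object_id))),
      n_relations = length(unique(predications$predicate)),
      years = years
    ),
    class = "corpus_summary"
  )
}

#' @exportS3Method base::print
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus_summary> %d predications | %d distinct triples | %d entities | %d relations\n",
              x$n_predications, x$n_triples, x$n_entities, x$n_relations))
  invisible(x)
}
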