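# Internal helpers shared across modules.

# Canonical string key for a triple; used for set membership (dedup checks,
# filtered ranking, novelty flags). "\r" cannot occur in CUIs or predicates.
triple_key <- function(head, relation, tail) {
  paste(head, relation, tail, sep = "\r")
}

# Derive a reproducible per-stage seed from one global seed, so pipeline
# stages are independently re-runnable. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

# min-max rescale to [0, 1]; a constant vector maps to all zeros.
minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
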