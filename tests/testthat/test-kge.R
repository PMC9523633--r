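test_that("scoring functions satisfy their closed forms", {
  # TransE: exact translation scores 0 (its maximum)
  m <- random_kge_model("transe", n_ent = 3, n_rel = 1, dim = 2)
  m$ent[1, ] <- c(1, 0); m$rel[1, ] <- c(0, 1); m$ent[2, ] <- c(1, 1)
  expect_equal(kge_score(m, 1, 1, 2), 0)
  expect_lte(max(kge_score(m, 1:3, 1, c(2, 3, 1))), 0)

  # DistMult: all-ones embeddings score the dimension
  md <- random_kge_model("distmult", dim = 6)
  md$ent[1, ] <- 1; md$rel[1, ] <- 1; md$ent[2, ] <- 1
  expect_equal(kge_score(md, 1, 1, 2), 6)

  # ComplEx with zero imaginary parts equals DistMult on the real parts
  mc <- random_kge_model("complex", dim = 4, seed = 3)
  mc$ent_im[] <- 0; mc$rel_im[] <- 0
  md2 <- random_kge_model("distmult", dim = 4, seed = 99)
  md2$ent <- mc$ent_re; md2$rel <- mc$rel_re
  h <- c(1, 2, 3); r <- c(1, 2, 1); t <- c(2, 3, 1)
  expect_identical(kge_score(mc, h, r, t), kge_score(md2, h, r, t))

  expect_error(kge_score(md, 1, 1, 99), "out of range")
})

test_that("vectorized scores match a naive per-coordinate loop", {
  for (family in c("transe", "distmult", "complex")) {
    for (seed in 1:3) {
      m <- random_kge_model(family, n_ent = 6, n_rel = 3, dim = 5, seed = seed)
      set.seed(seed + 100)
      h <- sample.int(6, 10, TRUE); r <- sample.int(3, 10, TRUE)
      t <- sample.int(6, 10, TRUE)
      got <- kge_score(m, h, r, t)
      want <- vapply(1:10, function(i) naive_score(m, h[i], r[i], t[i]),
                     numeric(1))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
  # L1 TransE too
  m1 <- random_kge_model("transe", dim = 4, seed = 9, norm_order = 1)
  expect_equal(kge_score(m1, 1, 1, 2), naive_score(m1, 1, 1, 2),
               tolerance = 1e-12)
})

test_that("DistMult is symmetric; ComplEx reduces and is antisymmetric, exactly", {
  set.seed(31)
  for (i in 1:200) {
    md <- random_kge_model("distmult", n_ent = 4, n_rel = 2, dim = 3,
                           seed = 1000 + i)
    h <- sample.int(4, 1); r <- sample.int(2, 1); t <- sample.int(4, 1)
    expect_identical(kge_score(md, h, r, t), kge_score(md, t, r, h))

    mc <- random_kge_model("complex", n_ent = 4, n_rel = 2, dim = 3,
                           seed = 2000 + i)
    mc$rel_re[] <- 0   # purely imaginary relations: exact antisymmetry
    expect_identical(kge_score(mc, h, r, t), -kge_score(mc, t, r, h))
  }
})

test_that("negative sampling corrupts one slot uniformly, never to the original", {
  set.seed(41)
  # only one alternative with two entities
  neg <- corrupt_triples(1L, 1L, 2L, n_entities = 2, k = 50)
  expect_true(all(ifelse(neg$corrupt_head, neg$h == 2L, neg$t == 1L)))
  expect_true(all(neg$r == 1L))

  # corrupted entity never equals the original; relation unchanged
  h <- sample.int(20, 200, TRUE); r <- sample.int(3, 200, TRUE)
  t <- sample.int(20, 200, TRUE)
  neg2 <- corrupt_triples(h, r, t, n_entities = 20, k = 2)
  src <- neg2$source
  expect_true(all(ifelse(neg2$corrupt_head,
                         neg2$h != h[src] & neg2$t == t[src],
                         neg2$t != t[src] & neg2$h == h[src])))
  expect_identical(neg2$r, r[src])

  # fair head/tail coin over 10,000 draws
  set.seed(42)
  neg3 <- corrupt_triples(rep(1L, 10000), rep(1L, 10000), rep(2L, 10000),
                          n_entities = 50, k = 1)
  expect_equal(mean(neg3$corrupt_head), 0.5, tolerance = 0.02)

  expect_error(corrupt_triples(1L, 1L, 1L, n_entities = 1), "at least 2")
})

test_that("logistic loss matches its closed form and stays stable at large scores", {
  expect_equal(logistic_loss(0, 1), log(2), tolerance = 1e-12)
  expect_equal(logistic_loss(1000, 1), 0, tolerance = 1e-12)
  expect_equal(logistic_loss(1000, -1), 1000, tolerance = 1e-9)
  expect_equal(logistic_loss(-1000, -1), 0, tolerance = 1e-12)

  set.seed(51)
  f <- runif(50, -30, 30); y <- sample(c(-1, 1), 50, TRUE)
  naive <- sum(log(1 + exp(-y * f)))
  expect_equal(logistic_loss(f, y), naive, tolerance = 1e-9)
  expect_error(logistic_loss(1, 2), "labels")
})

test_that("analytic gradients agree with central finite differences", {
  expect_lt(gradient_check("transe", dim = 6, seed = 1), 1e-4)
  expect_lt(gradient_check("transe", dim = 6, seed = 2, norm_order = 1), 1e-4)
  expect_lt(gradient_check("distmult", dim = 6, seed = 1), 1e-4)
  expect_lt(gradient_check("complex", dim = 6, seed = 1), 1e-4)
})

test_that("training is deterministic, learns a trivial objective, and reduces loss", {
  tr <- tibble::tibble(head = c("a", "b", "c", "a"),
                       relation = c("R", "R", "R", "S"),
                       tail = c("b", "c", "a", "c"))
  m1 <- kge_train(tr, "transe", dim = 4, epochs = 30, seed = 7)
  m2 <- kge_train(tr, "transe", dim = 4, epochs = 30, seed = 7)
  expect_identical(m1$ent, m2$ent)
  expect_identical(m1$rel, m2$rel)
  expect_identical(m1$loss_trace, m2$loss_trace)

  # single triple, two entities: the translation becomes near-exact
  one <- tibble::tibble(head = "a", relation = "R", tail = "b")
  ms <- kge_train(one, "transe", dim = 4, epochs = 2500, batch_size = 1,
                  seed = 1)
  expect_gt(kge_score(ms, "a", "R", "b"), -0.2)

  # mean loss over the last quartile of epochs is below the first quartile
  kg <- generate_kg(synthetic_config(n_entities = 80, seed = 8))
  triples <- deduplicate_predications(kg$predications)
  for (family in c("transe", "distmult", "complex")) {
    m <- kge_train(triples, family, dim = 8, epochs = 40, seed = 2)
    q <- nrow(m$loss_trace) %/% 4
    expect_lt(mean(m$loss_trace$loss[(40 - q + 1):40]),
              mean(m$loss_trace$loss[1:q]))
    # TransE keeps unit entity norms
    if (family == "transe") {
      expect_equal(unname(sqrt(rowSums(m$ent^2))),
                   rep(1, length(m$entities)), tolerance = 1e-8)
    }
  }
  expect_error(kge_train(tr, "transe", learning_rate = 0), "learning_rate")
  expect_error(kge_train(tr[0, ], "transe"), "empty")
})

test_that("model checkpoints round-trip through the text format", {
  tr <- tibble::tibble(head = c("a", "b"), relation = "R", tail = c("b", "a"))
  for (family in c("transe", "complex")) {
    m <- kge_train(tr, family, dim = 3, epochs = 5, seed = 3)
    dir <- withr::local_tempdir()
    write_kge_model(m, dir)
    m2 <- read_kge_model(dir)
    expect_equal(kge_score(m2, "a", "R", "b"), kge_score(m, "a", "R", "b"),
                 tolerance = 1e-12)
    expect_equal(m2$entities, m$entities)
    expect_equal(m2$family, m$family)
  }
})
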