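test_that("semantic-type filter removes blocked groups and conserves records", {
  recs <- random_predications(10, seed = 1)
  recs$subject_semtype[1] <- "cnce"   # Concepts & Ideas
  recs$object_semtype[2] <- "acty"    # Activities & Behaviors
  recs$subject_semtype[3:10] <- "phsu"
  recs$object_semtype[c(1, 3:10)] <- "dsyn"
  out <- semantic_type_filter(recs)
  expect_equal(nrow(out$retained) + nrow(out$removed), 10)
  expect_true(all(c(1, 2) %in% which(recs$pmid %in% out$removed$pmid)))

  # empty blocklist is the identity
  out2 <- semantic_type_filter(recs, blocklist = character())
  expect_equal(nrow(out2$retained), 10)
  expect_equal(nrow(out2$removed), 0)
})

test_that("semantic-type filter matches a per-record brute-force check", {
  gm <- semantic_group_map()
  lookup <- setNames(gm$group, gm$semtype)
  for (seed in 1:8) {
    recs <- random_predications(40, seed = seed)
    block <- sample(unique(gm$group), 3)
    out <- suppressMessages(semantic_type_filter(recs, block, gm))
    manual <- vapply(seq_len(nrow(recs)), function(i) {
      sg <- lookup[recs$subject_semtype[i]]
      og <- lookup[recs$object_semtype[i]]
      isTRUE(sg %in% block) || isTRUE(og %in% block)
    }, logical(1))
    expect_equal(nrow(out$removed), sum(manual))
    expect_equal(nrow(out$retained) + nrow(out$removed), nrow(recs))
  }
})

test_that("degree centrality equals adjacency row and column sums", {
  # 2-cycle: A->B, B->A
  g <- build_graph(tibble::tibble(head = c("A", "B"), relation = "R",
                                  tail = c("B", "A")))
  ct <- degree_centrality(g)
  expect_equal(ct$a_in, c(1, 1))
  expect_equal(ct$a_out, c(1, 1))

  # two distinct relations A->B: a_out(A)=2, a_in(B)=2
  g2 <- build_graph(tibble::tibble(head = "A", relation = c("R1", "R2"),
                                   tail = "B"))
  ct2 <- degree_centrality(g2)
  expect_equal(ct2$a_out, c(2, 0))
  expect_equal(ct2$a_in, c(0, 2))

  # random sparse graph vs dense-matrix oracle
  recs <- random_predications(100, n_entities = 9, seed = 3)
  tr <- deduplicate_predications(recs)
  g3 <- build_graph(tr)
  dense <- as.matrix(g3$adjacency)
  ct3 <- degree_centrality(g3)
  expect_equal(ct3$a_out, unname(rowSums(dense)))
  expect_equal(ct3$a_in, unname(colSums(dense)))
  expect_equal(sum(ct3$a_in), sum(ct3$a_out))
})

test_that("independence expectations are products of marginals over N^(k-1)", {
  # uniform table is its own expectation
  u <- independence_expectation(matrix(5, 2, 2))
  expect_equal(u$expected, array(5, c(2, 2)))

  # hand-computed marginal products: rows (30,70) x cols (40,60) / 100
  tb <- independence_expectation(matrix(c(10, 30, 20, 40), 2, 2))
  expect_equal(tb$expected, array(c(12, 28, 18, 42), c(2, 2)))
  expect_equal(sum(tb$expected), tb$total)

  # any outer product of positive marginals is exactly independent, incl. 3-way
  set.seed(4)
  m1 <- rgamma(2, 5); m2 <- rgamma(3, 5); m3 <- rgamma(2, 5)
  o3 <- array(Reduce(`%o%`, list(m1, m2, m3)), c(2, 3, 2))
  ex <- independence_expectation(o3)
  expect_equal(ex$expected, o3, tolerance = 1e-12)
  expect_equal(g_squared(ex), 0, tolerance = 1e-12)

  expect_error(independence_expectation(matrix(0, 2, 2)), "positive")
})

test_that("G-squared matches its closed form and the log-linear deviance", {
  # exact independence gives zero
  expect_equal(g_squared(matrix(c(12, 28, 18, 42), 2, 2)), 0, tolerance = 1e-12)

  # hand example: 2 * sum O log(O/E) for [[10,20],[30,40]]
  hand <- 2 * (10 * log(10 / 12) + 20 * log(20 / 18) +
                 30 * log(30 / 28) + 40 * log(40 / 42))
  expect_equal(g_squared(matrix(c(10, 30, 20, 40), 2, 2)), hand,
               tolerance = 1e-12)
  expect_equal(hand, 0.8043, tolerance = 1e-4)

  # cross-implementation: base R's log-linear model LRT
  set.seed(5)
  for (i in 1:20) {
    o <- matrix(rpois(4, 20) + 1, 2, 2)
    ll <- loglin(o, margin = list(1, 2), fit = FALSE, print = FALSE)
    expect_equal(g_squared(o), ll$lrt, tolerance = 1e-9)
  }

  # zero observed cells contribute zero
  o <- matrix(c(0, 5, 5, 5), 2, 2)
  expect_equal(g_squared(o),
               loglin(o, list(1, 2), print = FALSE)$lrt, tolerance = 1e-9)
})

test_that("G-squared is transpose-invariant and scales linearly with counts", {
  set.seed(6)
  for (i in 1:10) {
    o <- matrix(rpois(6, 15) + 1, 2, 3)
    expect_equal(g_squared(o), g_squared(t(o)), tolerance = 1e-12)
    c_int <- sample(2:6, 1)
    expect_equal(g_squared(c_int * o), c_int * g_squared(o), tolerance = 1e-9)
  }
})

test_that("pair association builds the 2x2 mention table per subject-object pair", {
  # perfect association dominates all other pairs
  recs <- random_predications(0, seed = 1)
  mk <- function(s, o, n) tibble::tibble(
    subject_id = rep(s, n), subject_name = s, subject_semtype = "phsu",
    predicate = "TREATS", object_id = rep(o, n), object_name = o,
    object_semtype = "dsyn", pmid = "1", year = 2010L, sentence = ""
  )
  corpus <- dplyr::bind_rows(mk("S", "O", 10), mk("A", "B", 3), mk("A", "C", 3),
                             mk("D", "B", 3), mk("D", "C", 3))
  pa <- pair_association(corpus)
  top <- pa[which.max(pa$g2), ]
  expect_equal(top$subject_id, "S")
  expect_equal(top$object_id, "O")

  # a pair occurring exactly at the independence rate gives zero
  balanced <- dplyr::bind_rows(mk("A", "B", 3), mk("A", "C", 3),
                               mk("D", "B", 3), mk("D", "C", 3))
  pa2 <- pair_association(balanced)
  expect_lt(max(pa2$g2), 1e-9)
})

test_that("pair association matches brute-force co-occurrence counting", {
  for (seed in 1:5) {
    recs <- random_predications(60, n_entities = 6, seed = seed)
    pa <- pair_association(recs)
    n <- nrow(recs)
    for (i in sample.int(nrow(pa), min(8, nrow(pa)))) {
      s <- pa$subject_id[i]; o <- pa$object_id[i]
      a <- sum(recs$subject_id == s & recs$object_id == o)
      b <- sum(recs$subject_id == s & recs$object_id != o)
      cc <- sum(recs$subject_id != s & recs$object_id == o)
      d <- n - a - b - cc
      expect_equal(pa$g2[i], g_squared(matrix(c(a, cc, b, d), 2, 2)),
                   tolerance = 1e-9)
    }
  }
})

test_that("composite scores min-max normalize and sum the three components", {
  tr <- tibble::tibble(head = c("A", "B"), relation = "R", tail = c("X", "Y"))
  ct <- tibble::tibble(entity = c("A", "B", "X", "Y"),
                       a_out = c(1, 3, 0, 0), a_in = c(0, 0, 1, 3))
  pa <- tibble::tibble(subject_id = c("A", "B"), object_id = c("X", "Y"),
                       g2 = c(1, 3))
  sc <- composite_scores(tr, ct, pa)
  expect_equal(sc$composite, c(0, 3))

  # single triple: constant components normalize to zero
  sc1 <- composite_scores(tr[1, ], ct, pa)
  expect_equal(sc1$composite, 0)

  # random scores: ordering matches direct recomputation
  set.seed(8)
  n <- 20
  tr2 <- tibble::tibble(head = sprintf("h%d", 1:n), relation = "R",
                        tail = sprintf("t%d", 1:n))
  ct2 <- tibble::tibble(entity = c(tr2$head, tr2$tail),
                        a_out = c(runif(n), rep(0, n)),
                        a_in = c(rep(0, n), runif(n)))
  pa2 <- tibble::tibble(subject_id = tr2$head, object_id = tr2$tail,
                        g2 = runif(n))
  sc2 <- composite_scores(tr2, ct2, pa2)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  manual <- mm(ct2$a_out[1:n]) + mm(ct2$a_in[n + 1:n]) + mm(pa2$g2)
  expect_equal(sc2$composite, manual)
  expect_true(all(sc2$norm_g2 >= 0 & sc2$norm_g2 <= 1))

  expect_error(composite_scores(tr, ct[1:2, ], pa), "centrality")
})

test_that("top-k selection preserves the whitelist and matches the sorting oracle", {
  set.seed(9)
  n <- 30
  scored <- tibble::tibble(
    head = sprintf("h%02d", sample(n)), relation = "R",
    tail = sprintf("t%02d", sample(n)), composite = round(runif(n), 2)
  )
  wl <- c(scored$head[1:2], scored$tail[3])

  # whitelist overrides k, including k = 0
  kept0 <- select_top_k(scored, 0, whitelist = wl)
  expect_equal(nrow(kept0), 3)
  expect_true(all(kept0$head %in% wl | kept0$tail %in% wl))

  # k = n with empty whitelist is the identity
  expect_equal(nrow(select_top_k(scored, n)), n)

  # brute-force sort-and-slice oracle with the stated tie-break
  for (k in c(5, 15, 29)) {
    kept <- select_top_k(scored, k, whitelist = wl)
    white <- scored$head %in% wl | scored$tail %in% wl
    rest <- scored[!white, ]
    ord <- order(-rest$composite, rest$head, rest$relation, rest$tail)
    expected <- dplyr::bind_rows(scored[white, ],
                                 rest[utils::head(ord, max(k - sum(white), 0)), ])
    expect_equal(triple_set(kept), triple_set(expected))
    expect_equal(nrow(kept), min(max(k, sum(white)), n))
  }

  # monotonicity: growing k never drops a retained triple
  prev <- select_top_k(scored, 4, whitelist = wl)
  for (k in c(8, 16, 32)) {
    cur <- select_top_k(scored, k, whitelist = wl)
    expect_true(all(triple_set(prev) %in% triple_set(cur)))
    prev <- cur
  }
})

test_that("concept lists read newline-delimited files with comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# disease concepts", "C0002395", "", "C0011265 "), path)
  expect_equal(read_concept_list(path), c("C0002395", "C0011265"))
})
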