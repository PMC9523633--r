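test_that("predication IO round-trips through the SemMedDB dialect", {
  recs <- random_predications(25, seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  n <- write_predications(recs, path)
  expect_equal(n, 25)
  back <- read_predications(path)
  expect_equal(as.data.frame(back), as.data.frame(recs), ignore_attr = TRUE)

  # empty sequence: header-only file, zero rows back
  path2 <- withr::local_tempfile(fileext = ".tsv")
  expect_equal(write_predications(recs[0, ], path2), 0)
  expect_equal(nrow(read_predications(path2)), 0)
})

test_that("rows with empty identifiers are skipped and counted; bad years kept as NA", {
  recs <- random_predications(6, seed = 102, p_missing_year = 0)
  raw <- recs
  raw$object_id[2] <- ""
  raw$subject_id[5] <- ""
  path <- withr::local_tempfile(fileext = ".csv")
  write_predications(raw, path)
  expect_message(back <- read_predications(path), "skipped 2")
  expect_equal(nrow(back), 4)
  expect_equal(attr(back, "n_skipped"), 2)

  # unparseable year: row kept, year missing
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  tab$YEAR[1] <- "not-a-year"
  readr::write_csv(tab, path)
  back2 <- suppressMessages(read_predications(path))
  expect_true(is.na(back2$year[1]))
  expect_equal(nrow(back2), 4)

  expect_error(read_predications(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("deduplication merges mentions, keeps the earliest year, splits by predicate", {
  recs <- tibble::tibble(
    subject_id = c("A", "A", "A"), subject_name = "a", subject_semtype = "phsu",
    predicate = c("TREATS", "TREATS", "PREVENTS"),
    object_id = "B", object_name = "b", object_semtype = "dsyn",
    pmid = c("1", "2", "3"), year = c(2018L, 2010L, NA),
    sentence = ""
  )
  tr <- deduplicate_predications(recs)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$first_year[tr$relation == "TREATS"], 2010L)
  expect_true(is.na(tr$first_year[tr$relation == "PREVENTS"]))
})

test_that("deduplication matches a brute-force group-by oracle on random corpora", {
  for (seed in 1:5) {
    recs <- random_predications(80, n_entities = 8, seed = seed)
    tr <- deduplicate_predications(recs)
    key <- paste(recs$subject_id, recs$predicate, recs$object_id)
    expect_equal(nrow(tr), length(unique(key)))
    agg <- tapply(recs$year, key, function(y) {
      if (all(is.na(y))) NA_integer_ else min(y, na.rm = TRUE)
    })
    agg <- setNames(as.integer(agg), names(agg))
    got <- setNames(tr$first_year, paste(tr$head, tr$relation, tr$tail))
    expect_equal(got[names(agg)], agg)
    expect_lte(nrow(tr), nrow(recs))
  }
})

test_that("dedup is idempotent when triples are lifted back to predications", {
  recs <- random_predications(60, n_entities = 7, seed = 7)
  tr <- deduplicate_predications(recs)
  lifted <- tibble::tibble(
    subject_id = tr$head, subject_name = tr$head, subject_semtype = "phsu",
    predicate = tr$relation, object_id = tr$tail, object_name = tr$tail,
    object_semtype = "dsyn", pmid = "0", year = tr$first_year, sentence = ""
  )
  tr2 <- deduplicate_predications(lifted)
  expect_equal(tr2[, c("head", "relation", "tail", "first_year")],
               tr[, c("head", "relation", "tail", "first_year")])
})

test_that("build_graph indexes entities and counts head-tail adjacency", {
  tr <- tibble::tibble(head = c("A", "A"), relation = c("R1", "R2"),
                       tail = c("B", "B"))
  g <- build_graph(tr)
  expect_equal(as.numeric(g$adjacency["A", "B"]), 2)
  expect_equal(g$entities, c("A", "B"))
  expect_equal(sum(g$adjacency), nrow(tr))

  # empty graph
  g0 <- build_graph(tr[0, ])
  expect_equal(length(g0$entities), 0)
  expect_equal(dim(g0$adjacency), c(0L, 0L))

  # duplicates violate the precondition
  expect_error(build_graph(tr[c(1, 1), ]), "duplicated")
})

test_that("adjacency row/column sums match brute-force out/in triple counts", {
  set.seed(11)
  recs <- random_predications(120, n_entities = 10, seed = 11)
  tr <- deduplicate_predications(recs)
  g <- build_graph(tr)
  out_counts <- table(factor(tr$head, levels = g$entities))
  in_counts <- table(factor(tr$tail, levels = g$entities))
  expect_equal(as.numeric(Matrix::rowSums(g$adjacency)), as.numeric(out_counts))
  expect_equal(as.numeric(Matrix::colSums(g$adjacency)), as.numeric(in_counts))
  # graph round-trip: stored triples reproduce the input set
  expect_equal(triple_set(g$triples), triple_set(tr))
  # binary mode caps entries at 1
  gb <- build_graph(tr, adjacency = "binary")
  expect_true(all(gb$adjacency@x <= 1))
})

test_that("temporal split respects the year boundaries", {
  tr <- tibble::tibble(head = c("a", "b", "c"), relation = "R",
                       tail = c("x", "y", "z"),
                       first_year = c(2015L, 2019L, 2021L))
  sp <- temporal_split(tr, train_before = 2019, valid_through = 2020)
  expect_equal(sp$train$first_year, 2015L)
  expect_equal(sp$validation$first_year, 2019L)
  expect_equal(sp$test$first_year, 2021L)

  sp2 <- temporal_split(dplyr::mutate(tr, first_year = c(2000L, 2005L, 2010L)))
  expect_equal(nrow(sp2$validation), 0)
  expect_equal(nrow(sp2$test), 0)
  expect_error(temporal_split(tr, train_before = 2023, valid_through = 2020),
               "train_before")
})

test_that("temporal split partitions conservatively and matches bucket counting", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 50
    tr <- tibble::tibble(
      head = sprintf("h%d", 1:n), relation = "R", tail = sprintf("t%d", 1:n),
      first_year = ifelse(runif(n) < 0.15, NA_integer_,
                          sample(2000:2023, n, replace = TRUE))
    )
    sp <- temporal_split(tr, 2019, 2020)
    expect_equal(nrow(sp$train) + nrow(sp$validation) + nrow(sp$test) +
                   sp$n_excluded, n)
    expect_equal(nrow(sp$train), sum(tr$first_year < 2019, na.rm = TRUE))
    expect_equal(nrow(sp$validation),
                 sum(tr$first_year >= 2019 & tr$first_year <= 2020, na.rm = TRUE))
    expect_equal(nrow(sp$test), sum(tr$first_year > 2020, na.rm = TRUE))
    expect_equal(sp$n_excluded, sum(is.na(tr$first_year)))
    expect_equal(tidy(sp)$n[4], sp$n_excluded)
  }
})
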