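#' Column mapping for the SemMedDB PREDICATION-table dialect
#'
#' A predication file is any delimited table with one subject--predicate--object
#' assertion per row. The dialect maps the nine predication fields (plus
#' publication year) onto the file's column names. The default follows the
#' SemMedDB PREDICATION table, flattened so that the publication year of the
#' source citation is a `YEAR` column rather than a join against the
#' SENTENCE/CITATIONS tables.
#'
#' @param subject_id,subject_name,subject_semtype Column names for the subject
#'   concept identifier (CUI), preferred name, and semantic-type code.
#' @param predicate Column name for the relation label (e.g. `TREATS`).
#' @param object_id,object_name,object_semtype As for the subject.
#' @param pmid Column name for the source-document identifier.
#' @param year Column name for the publication year.
#' @param sentence Column name for the source sentence (may be absent).
#' @return A named character vector mapping predication fields to file columns.
#' @examples
#' semmeddb_dialect()
#' @export
semmeddb_dialect <- function(subject_id = "SUBJECT_CUI",
                             subject_name = "SUBJECT_NAME",
                             subject_semtype = "SUBJECT_SEMTYPE",
                             predicate = "PREDICATE",
                             object_id = "OBJECT_CUI",
                             object_name = "OBJECT_NAME",
                             object_semtype = "OBJECT_SEMTYPE",
                             pmid = "PMID",
                             year = "YEAR",
                             sentence = "SENTENCE") {
  c(subject_id = subject_id, subject_name = subject_name,
    subject_semtype = subject_semtype, predicate = predicate,
    object_id = object_id, object_name = object_name,
    object_semtype = object_semtype, pmid = pmid, year = year,
    sentence = sentence)
}

predication_fields <- function() {
  c("subject_id", "subject_name", "subject_semtype", "predicate",
    "object_id", "object_name", "object_semtype", "pmid", "year", "sentence")
}

guess_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read semantic predications from a delimited file
#'
#' Reads one predication per row. Rows with an empty subject identifier,
#' predicate, or object identifier are skipped (the skip count is reported
#' via a message). A year that fails to parse is set to `NA` and the row
#' is kept.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param dialect Named character vector mapping predication fields to column
#'   names; see [semmeddb_dialect()].
#' @param delim Field delimiter; default guessed from the file extension
#'   (`.tsv` means tab, otherwise comma).
#' @return A tibble with columns `subject_id`, `subject_name`,
#'   `subject_semtype`, `predicate`, `object_id`, `object_name`,
#'   `object_semtype`, `pmid`, `year` (integer, `NA` when missing),
#'   `sentence`.
#' @seealso [write_predications()], [deduplicate_predications()]
#' @export
read_predications <- function(path, dialect = semmeddb_dialect(), delim = NULL) {
  if (!file.exists(path)) abort(sprintf("predication file not found: %s", path))
  delim <- guess_delim(path, delim)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  needed <- dialect[setdiff(names(dialect), "sentence")]
  missing <- setdiff(unname(needed), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("file lacks dialect column(s): %s", paste(missing, collapse = ", ")))
  }
  out <- tibble(
    subject_id = raw[[dialect[["subject_id"]]]],
    subject_name = raw[[dialect[["subject_name"]]]],
    subject_semtype = raw[[dialect[["subject_semtype"]]]],
    predicate = raw[[dialect[["predicate"]]]],
    object_id = raw[[dialect[["object_id"]]]],
    object_name = raw[[dialect[["object_name"]]]],
    object_semtype = raw[[dialect[["object_semtype"]]]],
    pmid = raw[[dialect[["pmid"]]]],
    year = suppressWarnings(as.integer(raw[[dialect[["year"]]]])),
    sentence = if (dialect[["sentence"]] %in% names(raw)) raw[[dialect[["sentence"]]]] else NA_character_
  )
  out$year[!is.na(out$year) & out$year <= 0] <- NA_integer_
  keep <- !is.na(out$subject_id) & out$subject_id != "" &
    !is.na(out$predicate) & out$predicate != "" &
    !is.na(out$object_id) & out$object_id != ""
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("read_predications: skipped %d row(s) with empty subject/predicate/object", n_skipped))
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write semantic predications to a delimited file
#'
#' Inverse of [read_predications()]: writes the predication tibble under the
#' column names given by `dialect`, so that reading the file back yields the
#' same records.
#'
#' @param records Predication tibble (see [read_predications()] for columns).
#' @param path Output file path.
#' @inheritParams read_predications
#' @return The number of rows written, invisibly.
#' @export
write_predications <- function(records, path, dialect = semmeddb_dialect(),
                               delim = NULL) {
  assert_columns(records, predication_fields(), "records")
  delim <- guess_delim(path, delim)
  out <- records[, predication_fields()]
  names(out) <- unname(dialect[predication_fields()])
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(nrow(out))
}

#' Deduplicate predications into distinct triples
#'
#' Collapses predication mentions to one row per distinct
#' (subject, predicate, object) triple, recording the earliest publication
#' year among the merged mentions (`first_year`). Mentions with missing
#' years are ignored when taking the minimum; a triple whose mentions all
#' lack a year gets `first_year = NA`.
#'
#' @param records Predication tibble.
#' @return A tibble of triples with columns `head`, `relation`, `tail`,
#'   `first_year`, and `n_mentions` (how many predication rows merged).
#' @export
deduplicate_predications <- function(records) {
  assert_columns(records, c("subject_id", "predicate", "object_id"), "records")
  if (!"year" %in% names(records)) records$year <- NA_integer_
  records |>
    group_by(head = .data$subject_id, relation = .data$predicate,
             tail = .data$object_id) |>
    summarise(
      first_year = if (all(is.na(.data$year))) NA_integer_ else
        as.integer(min(.data$year, na.rm = TRUE)),
      n_mentions = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$head, .data$relation, .data$tail)
}

#' Build a knowledge graph from deduplicated triples
#'
#' Indexes entities and relations densely (sorted, gap-free) and builds the
#' sparse head-by-tail adjacency matrix M whose entry (h, t) counts the
#' distinct triples linking h to t. Degree centrality and the association
#' filter are computed from M.
#'
#' @param triples Tibble with columns `head`, `relation`, `tail` (and
#'   optionally `first_year`); must contain no duplicated (head, relation,
#'   tail) rows -- run [deduplicate_predications()] first.
#' @param adjacency `"count"` (default) counts distinct triples per
#'   head--tail pair; `"binary"` records 0/1 incidence instead.
#' @return An object of class `knowledge_graph`: a list with `triples`
#'   (the input plus integer `head_id`, `relation_id`, `tail_id`),
#'   `entities` and `relations` (the index-ordered label vectors), and
#'   `adjacency` (a sparse `Matrix`).
#' @export
build_graph <- function(triples, adjacency = c("count", "binary")) {
  adjacency <- match.arg(adjacency)
  assert_columns(triples, c("head", "relation", "tail"), "triples")
  key <- triple_key(triples$head, triples$relation, triples$tail)
  if (anyDuplicated(key)) {
    abort("triples contain duplicated (head, relation, tail) rows; deduplicate first")
  }
  entities <- sort(unique(c(triples$head, triples$tail)))
  relations <- sort(unique(triples$relation))
  triples <- triples |>
    mutate(head_id = match(.data$head, entities),
           relation_id = match(.data$relation, relations),
           tail_id = match(.data$tail, entities))
  n <- length(entities)
  if (n == 0) {
    adj <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0L, 0L))
  } else {
    adj <- Matrix::sparseMatrix(i = triples$head_id, j = triples$tail_id,
                                x = 1, dims = c(n, n),
                                dimnames = list(entities, entities))
    if (adjacency == "binary") adj@x[adj@x > 0] <- 1
  }
  structure(
    list(triples = triples, entities = entities, relations = relations,
         adjacency = adj, adjacency_mode = adjacency),
    class = "knowledge_graph"
  )
}

#' @exportS3Method base::print
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d triples, %d entities, %d relations (adjacency: %s)\n",
              nrow(x$triples), length(x$entities), length(x$relations),
              x$adjacency_mode))
  invisible(x)
}

#' Split triples into train / validation / test slices by first year
#'
#' Time-slicing split: triples first published before `train_before` form
#' the training slice, those first published in
#' `[train_before, valid_through]` the validation slice, and those first
#' published after `valid_through` the test slice. The defaults train on
#' literature before 1 Jan 2019, validate on 2019--2020, and test on 2021
#' onwards. Triples with a missing `first_year` are excluded and counted.
#'
#' @param triples Tibble with columns `head`, `relation`, `tail`,
#'   `first_year`.
#' @param train_before Calendar year; training keeps `first_year <
#'   train_before`.
#' @param valid_through Last calendar year of the validation slice.
#' @return An object of class `temporal_split`: a list with tibbles
#'   `train`, `validation`, `test`, the boundary years, and
#'   `n_excluded` (missing-year triples dropped).
#' @export
temporal_split <- function(triples, train_before = 2019, valid_through = 2020) {
  assert_columns(triples, c("head", "relation", "tail", "first_year"), "triples")
  if (train_before > valid_through + 1) {
    abort("train_before must be at most valid_through + 1")
  }
  missing <- is.na(triples$first_year)
  kept <- triples[!missing, , drop = FALSE]
  structure(
    list(
      train = kept[kept$first_year < train_before, , drop = FALSE],
      validation = kept[kept$first_year >= train_before &
                          kept$first_year <= valid_through, , drop = FALSE],
      test = kept[kept$first_year > valid_through, , drop = FALSE],
      train_before = train_before,
      valid_through = valid_through,
      n_excluded = sum(missing)
    ),
    class = "temporal_split"
  )
}

#' @exportS3Method base::print
print.temporal_split <- function(x, ...) {
  cat(sprintf("<temporal_split> train (< %d): %d | validation (%d-%d): %d | test (> %d): %d | excluded (no year): %d\n",
              x$train_before, nrow(x$train), x$train_before, x$valid_through,
              nrow(x$validation), x$valid_through, nrow(x$test), x$n_excluded))
  invisible(x)
}

#' @rdname temporal_split
#' @param x A `temporal_split`.
#' @param ... Unused.
#' @export
tidy.temporal_split <- function(x, ...) {
  tibble(
    slice = c("train", "validation", "test", "excluded"),
    n = c(nrow(x$train), nrow(x$validation), nrow(x$test), x$n_excluded)
  )
}
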