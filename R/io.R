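#' Worked 20-person example dataset
#'
#' A small hypothetical achievement-test dataset bundled with the package:
#' 20 test-takers, three binary items (`A1`, `A2`, `A3`), three polytomous
#' items (`B1`, `B2`, `B3`) and the test score `X`. The A/B columns are
#' constructed to contrast deterministic, noisy and crossing response
#' patterns, and every estimator in the package has a known value on them,
#' which the test suite pins to three decimals.
#'
#' @returns A 20-row tibble with columns `test_taker`, `A1`..`B3`, `X`.
#' @examples
#' associate(table1(), B1, X)
#' @export
table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "dircor",
    mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    abort(sprintf("'%s' is empty.", path), class = "dircor_parse_error")
  }
  if (grepl("\t", first)) "\t" else ","
}

#' Read a two-column paired series from delimited text
#'
#' Reads a CSV/TSV file (delimiter sniffed from the header line) and builds
#' a [paired_series()] from two of its columns.
#'
#' @param path Path to a delimited text file with a header row.
#' @param g,x Column names (character) or positions (numeric) of the item
#'   and score columns.
#' @returns A `paired_series`.
#' @export
read_paired <- function(path, g, x) {
  tb <- read_delim_checked(path)
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(tb)) {
        abort(sprintf("Column index %s out of range for '%s'.", col, what),
          class = "dircor_parse_error")
      }
      tb[[col]]
    } else {
      if (!col %in% names(tb)) {
        abort(sprintf("No column named '%s' in '%s'.", col, path),
          class = "dircor_parse_error")
      }
      tb[[col]]
    }
  }
  paired_series(pick(g, "g"), pick(x, "x"))
}

read_delim_checked <- function(path) {
  delim <- sniff_delim(path)
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE)
  if (nrow(tb) == 0 || ncol(tb) == 0) {
    abort(sprintf("'%s' holds no data rows.", path), class = "dircor_parse_error")
  }
  tb
}

#' Read a person x item response matrix
#'
#' Reads delimited text (header row of item names, one row per person) into
#' a validated numeric matrix. Any missing or non-numeric cell is rejected
#' with a message naming its row and column.
#'
#' @param path Path to a CSV/TSV file.
#' @returns A numeric matrix with the header as column names.
#' @export
read_response_matrix <- function(path) {
  delim <- sniff_delim(path)
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tb) == 0 || ncol(tb) == 0) {
    abort(sprintf("'%s' holds no data rows.", path), class = "dircor_parse_error")
  }
  m <- matrix(NA_real_, nrow(tb), ncol(tb), dimnames = list(NULL, names(tb)))
  for (j in seq_len(ncol(tb))) {
    vals <- suppressWarnings(as.numeric(tb[[j]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric or missing cell at row %d, column '%s' of '%s'.",
        bad[1], names(tb)[j], path), class = "dircor_parse_error")
    }
    m[, j] <- vals
  }
  m
}

#' Write a response matrix (or any table) as delimited text
#'
#' @param m A matrix or data frame.
#' @param path Output path; a `.tsv` extension selects tab, otherwise comma.
#' @returns `path`, invisibly.
#' @export
write_response_matrix <- function(m, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(as_tibble(as.data.frame(m)), path, delim = delim)
  invisible(path)
}

#' Write a test collection to a directory
#'
#' Writes each test's response matrix as `test_<i>.csv`, the item metadata
#' as `items.tsv`, and a plain-text `manifest.txt` echoing the generating
#' specification and seed, so a run is reproducible from its artifacts
#' alone.
#'
#' @param collection A `test_collection` from [generate_test_collection()].
#' @param dir Output directory (created if needed).
#' @returns `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "test_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(collection$responses)) {
    write_response_matrix(collection$responses[[i]],
      file.path(dir, sprintf("test_%03d.csv", i)))
  }
  readr::write_tsv(collection$meta, file.path(dir, "items.tsv"))
  spec <- collection$spec
  lines <- c(
    sprintf("n_tests: %d", spec$n_tests),
    sprintf("n_persons: %s", paste(spec$n_persons, collapse = ",")),
    sprintf("n_items: %d-%d", spec$n_items[1], spec$n_items[2]),
    sprintf("n_categories: %d-%d", spec$n_categories[1], spec$n_categories[2]),
    sprintf("difficulty: %g-%g", spec$difficulty[1], spec$difficulty[2]),
    sprintf("loading: %g-%g", spec$loading[1], spec$loading[2]),
    sprintf("latent_distribution: %s", spec$latent_distribution),
    sprintf("seed: %d", spec$seed))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
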