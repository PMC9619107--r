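#' Paired item/score series
#'
#' A `paired_series` is the unit of all bivariate estimation in dircor: two
#' equal-length, complete observation vectors. `g` is the ordinal variable
#' with the narrower scale (an "item": non-negative integer categories
#' `0..R-1` after coding) and `x` is the metric variable with the wider scale
#' (a "score"). Construction validates lengths, missingness and the coding
#' of `g`; every estimator in the package takes the resulting object first,
#' so calls chain naturally with the pipe.
#'
#' @param g Ordinal values: a non-negative integer-valued numeric vector, a
#'   logical vector, or a factor. An ordered factor (or any factor with
#'   exactly two levels) is converted to integer codes `0..R-1`; an unordered
#'   factor with more than two levels is rejected, because the directional
#'   estimators here require an ordinal `g`.
#' @param x Metric values (numeric), same length as `g`.
#' @returns A tibble of class `paired_series` with columns `g` and `x`.
#' @examples
#' pair <- paired_series(c(0, 0, 1, 1), c(1.2, 0.8, 2.5, 3.1))
#' pmc(pair)
#' @seealso [pair_columns()] to pull the two columns out of a data frame,
#'   [pair_from_table()] to expand an R x C contingency table.
#' @export
paired_series <- function(g, x) {
  g <- code_ordinal(g)
  x <- as.numeric(x)
  if (length(g) != length(x)) {
    abort("`g` and `x` must have the same length.", class = "dircor_invalid_input")
  }
  if (length(g) < 2) {
    abort("A paired series needs at least 2 observations.", class = "dircor_invalid_input")
  }
  if (anyNA(g) || anyNA(x) || any(!is.finite(g)) || any(!is.finite(x))) {
    abort("Missing or non-finite values are not allowed in a paired series.",
      class = "dircor_invalid_input")
  }
  new_paired_series(g, x)
}

new_paired_series <- function(g, x) {
  out <- tibble(g = g, x = x)
  class(out) <- c("paired_series", class(out))
  out
}

# Coerce the ordinal variable to non-negative integer codes.
code_ordinal <- function(g) {
  if (is.factor(g)) {
    if (!is.ordered(g) && nlevels(g) > 2) {
      abort(paste0(
        "`g` is an unordered factor with more than two levels; the ",
        "directional estimators need an ordinal `g`. Use an ordered factor ",
        "or integer codes."), class = "dircor_invalid_input")
    }
    return(as.integer(g) - 1L)
  }
  if (is.logical(g)) return(as.integer(g))
  g <- as.numeric(g)
  v <- g[!is.na(g) & is.finite(g)] # NAs are caught by the constructor
  if (any(v %% 1 != 0) || any(v < 0)) {
    abort("`g` must hold non-negative integer category values.",
      class = "dircor_invalid_input")
  }
  g
}

#' @export
print.paired_series <- function(x, ...) {
  cat(sprintf(
    "<paired_series: n = %d, item categories R = %d, score categories C = %d>\n",
    nrow(x), dplyr::n_distinct(x$g), dplyr::n_distinct(x$x)))
  NextMethod()
}

#' Build a paired series from two data-frame columns
#'
#' Tidy-eval front end to [paired_series()]: select the item and score
#' columns of a data frame by (unquoted) name.
#'
#' @param data A data frame holding the observations.
#' @param g,x Unquoted column names (or positions) of the ordinal item
#'   variable and the metric score variable.
#' @returns A `paired_series`.
#' @examples
#' pair_columns(table1(), A1, X)
#' @export
pair_columns <- function(data, g, x) {
  stopifnot(is.data.frame(data))
  gv <- dplyr::pull(data, {{ g }})
  xv <- dplyr::pull(data, {{ x }})
  paired_series(gv, xv)
}

#' Expand a contingency table to a paired series
#'
#' Ordinal measures such as gamma and Somers delta are often reported from an
#' R x C cross-table of the item (rows) against the score (columns). This
#' expands the cell counts back into observation pairs so that the same
#' estimator code path applies.
#'
#' @param tab A matrix or `table` of non-negative integer counts. Row and
#'   column names, when numeric, supply the category values; otherwise
#'   ranks `0..R-1` / `0..C-1` are used.
#' @returns A `paired_series`.
#' @export
pair_from_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab %% 1 != 0)) {
    abort("Contingency table cells must be non-negative integer counts.",
      class = "dircor_invalid_input")
  }
  rv <- numeric_labels(rownames(tab), nrow(tab))
  cv <- numeric_labels(colnames(tab), ncol(tab))
  idx <- which(tab > 0, arr.ind = TRUE)
  g <- rep(rv[idx[, 1]], tab[idx])
  x <- rep(cv[idx[, 2]], tab[idx])
  paired_series(g, x)
}

numeric_labels <- function(labels, k) {
  if (is.null(labels)) return(seq_len(k) - 1)
  vals <- suppressWarnings(as.numeric(labels))
  if (anyNA(vals)) seq_len(k) - 1 else vals
}

as_pair <- function(pair, arg = "pair") {
  if (!inherits(pair, "paired_series")) {
    abort(sprintf("`%s` must be a paired_series (see ?paired_series).", arg),
      class = "dircor_invalid_input")
  }
  pair
}

#' Item difficulty of an ordinal variable
#'
#' Difficulty is the mean divided by the maximum observed value: the
#' proportion correct for a binary item, and the analogous mean/max ratio for
#' a polytomous one.
#'
#' @param g Ordinal values (vector or `paired_series`).
#' @returns A single number in `[0, 1]`, or `NA` when `max(g) = 0`.
#' @export
difficulty <- function(g) {
  if (inherits(g, "paired_series")) g <- g$g
  m <- max(g)
  if (m == 0) return(NA_real_)
  mean(g) / m
}

new_estimate <- function(value, estimator, direction, n) {
  out <- tibble(estimator = estimator, direction = direction,
    value = as.numeric(value), n = as.integer(n))
  class(out) <- c("association_estimate", class(out))
  out
}

is_binary01 <- function(g) all(g %in% c(0, 1)) && dplyr::n_distinct(g) == 2
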