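# Population (divide-by-n) moments. The correlation is invariant to the
# n vs n-1 choice, but the point-biserial identity sd(g) = sqrt(p(1-p))
# only holds in the population form, so it is used throughout.
pop_var <- function(v) mean((v - mean(v))^2)
pop_sd <- function(v) sqrt(pop_var(v))
pop_cov <- function(a, b) mean((a - mean(a)) * (b - mean(b)))

check_nondegenerate <- function(v, label) {
  if (pop_var(v) == 0) {
    abort(sprintf("`%s` is constant: correlation is undefined on a degenerate input.",
      label), class = "dircor_degenerate_input")
  }
}

.pmc <- function(g, x) {
  check_nondegenerate(g, "g")
  check_nondegenerate(x, "x")
  as.numeric(cor(g, x))
}

#' Product-moment correlation
#'
#' The standardised covariance `cov(g, x) / (sd(g) sd(x))`, computed with
#' population moments. Symmetric in its two arguments as a number — but when
#' the scales of `g` and `x` differ, its value coincides with the
#' *directional* coefficient [eta()] in the `g_given_X` direction (exactly so
#' for binary `g`), which is why this package treats it as a directional
#' measure in disguise.
#'
#' @param pair A [paired_series()].
#' @returns A one-row tibble (`association_estimate`) with columns
#'   `estimator`, `direction`, `value`, `n`.
#' @examples
#' pmc(pair_columns(table1(), A1, X)) # 0.759
#' @export
pmc <- function(pair) {
  pair <- as_pair(pair)
  new_estimate(.pmc(pair$g, pair$x), "pmc", "not_applicable", nrow(pair))
}

#' Point-biserial correlation
#'
#' For a binary item `g` coded 0/1 against a metric score `x`, the
#' product-moment correlation reduces to
#' `(mean(x | g = 1) - mean(x | g = 0)) * sd(g) / sd(x)` with
#' `sd(g) = sqrt(p(1 - p))`. Identical to [pmc()] up to rounding error; the
#' closed form makes the directional reading explicit — the sign is carried
#' entirely by the difference of score means between the two item groups.
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble.
#' @export
point_biserial <- function(pair) {
  pair <- as_pair(pair)
  g <- pair$g
  if (!is_binary01(g)) {
    abort("point_biserial() requires `g` to take exactly the values {0, 1}.",
      class = "dircor_invalid_input")
  }
  check_nondegenerate(pair$x, "x")
  p <- mean(g)
  value <- (mean(pair$x[g == 1]) - mean(pair$x[g == 0])) * sqrt(p * (1 - p)) /
    pop_sd(pair$x)
  new_estimate(value, "point_biserial", "not_applicable", nrow(pair))
}

match_direction <- function(direction) {
  rlang::arg_match0(direction, c("g_given_X", "X_given_g"))
}

#' Between/within sum-of-squares decomposition
#'
#' Decomposes the total sum of squares of one variable of a pair over the
#' categories of the other. Direction `g_given_X` (the measurement-modelling
#' reading "the score explains the item") decomposes the score `x` over the
#' item categories of `g`; direction `X_given_g` decomposes the item `g` over
#' the distinct values of `x`. This decomposition is the backbone of
#' [eta()] and [eta_squared()], and `ss_between + ss_within = ss_total`
#' holds on every input.
#'
#' @inheritParams pmc
#' @param direction `"g_given_X"` or `"X_given_g"`.
#' @returns An object of class `ss_decomposition`: a list with elements
#'   `ss_between`, `ss_within`, `ss_total`, `grand_mean`, `group_means`
#'   (a tibble with `category`, `n`, `mean`), `direction`, `n`. `tidy()`
#'   returns the per-category means; `glance()` the one-row summary.
#' @examples
#' ss_decomposition(pair_columns(table1(), A3, X), "X_given_g")
#' @export
ss_decomposition <- function(pair, direction = c("g_given_X", "X_given_g")) {
  pair <- as_pair(pair)
  direction <- match_direction(direction[[1]])
  if (direction == "g_given_X") {
    values <- pair$x; groups <- pair$g
  } else {
    values <- pair$g; groups <- pair$x
  }
  gm <- mean(values)
  grp <- tibble(category = groups, value = values) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$category)
  ss_between <- sum(grp$n * (grp$mean - gm)^2)
  ss_total <- sum((values - gm)^2)
  structure(
    list(ss_between = ss_between, ss_within = ss_total - ss_between,
      ss_total = ss_total, grand_mean = gm, group_means = grp,
      direction = direction, n = nrow(pair)),
    class = "ss_decomposition")
}

#' @export
print.ss_decomposition <- function(x, ...) {
  cat(sprintf("<ss_decomposition: %s, %d groups>\n", x$direction, nrow(x$group_means)))
  cat(sprintf("  ss_between = %.6g, ss_within = %.6g, ss_total = %.6g\n",
    x$ss_between, x$ss_within, x$ss_total))
  invisible(x)
}

#' @rdname ss_decomposition
#' @param x An `ss_decomposition` object.
#' @param ... Unused.
#' @export
tidy.ss_decomposition <- function(x, ...) x$group_means

#' @rdname ss_decomposition
#' @export
glance.ss_decomposition <- function(x, ...) {
  tibble(direction = x$direction, ss_between = x$ss_between,
    ss_within = x$ss_within, ss_total = x$ss_total,
    eta_squared = x$ss_between / x$ss_total, n_groups = nrow(x$group_means),
    n = x$n)
}

#' Directional coefficient eta (correlation ratio)
#'
#' `sqrt(ss_between / ss_total)` from [ss_decomposition()]. Unlike the
#' product-moment correlation, eta is inherently directional: `g_given_X`
#' (often written eta1) groups the score by the item categories, and
#' `X_given_g` (eta2) groups the item by the distinct score values; the two
#' generally differ, and the gap between them widens with the discrepancy of
#' the two scales. For binary `g` the `g_given_X` value equals `|pmc|`
#' exactly; for polytomous ordinal `g` it is an upper bound for `|pmc|`.
#'
#' @inheritParams ss_decomposition
#' @returns A one-row `association_estimate` tibble with `value` in `[0, 1]`.
#' @examples
#' pair <- pair_columns(table1(), B1, X)
#' eta(pair, "g_given_X") # 0.820
#' eta(pair, "X_given_g") # 1
#' @export
eta <- function(pair, direction = c("g_given_X", "X_given_g")) {
  direction <- match_direction(direction[[1]])
  dec <- ss_decomposition(pair, direction)
  if (dec$ss_total == 0) {
    abort("The grouped variable has zero total sum of squares; eta is undefined.",
      class = "dircor_degenerate_input")
  }
  value <- sqrt(min(1, dec$ss_between / dec$ss_total))
  new_estimate(value, "eta", direction, dec$n)
}

#' @rdname eta
#' @returns `eta_squared()` returns the bare proportion
#'   `ss_between / ss_total` as a number.
#' @export
eta_squared <- function(pair, direction = c("g_given_X", "X_given_g")) {
  direction <- match_direction(direction[[1]])
  dec <- ss_decomposition(pair, direction)
  if (dec$ss_total == 0) {
    abort("The grouped variable has zero total sum of squares; eta is undefined.",
      class = "dircor_degenerate_input")
  }
  dec$ss_between / dec$ss_total
}

#' Signed eta
#'
#' The usual computation of eta squares every term, so it can only report the
#' magnitude of the association. For binary `g` the factual sign is that of
#' `mean(x | g = 1) - mean(x | g = 0)` (a reverse-coded item flips it); for
#' polytomous ordinal `g` no closed-form sign rule exists, and the sign of
#' the product-moment correlation is attached instead (a package convention,
#' documented in the methods vignette).
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble: magnitude
#'   `eta(pair, "g_given_X")`, sign as described.
#' @export
eta_signed <- function(pair) {
  pair <- as_pair(pair)
  est <- eta(pair, "g_given_X")
  s <- if (is_binary01(pair$g)) {
    sign(mean(pair$x[pair$g == 1]) - mean(pair$x[pair$g == 0]))
  } else {
    sign(.pmc(pair$g, pair$x))
  }
  if (s == 0) s <- 1
  new_estimate(s * est$value, "eta_signed", "g_given_X", nrow(pair))
}

#' Two-predictor multiple correlation
#'
#' Closed form for the multiple correlation of a dependent variable `y` on
#' two predictors `x` and `z` from the three bivariate correlations:
#' `R = sqrt((r_yx^2 + r_yz^2 - 2 r_yx r_yz r_xz) / (1 - r_xz^2))`.
#' Because each input correlation is deflated when scales differ, `R` and
#' `R^2` inherit that deflation.
#'
#' @param r_yx,r_yz Correlations of the dependent variable with each
#'   predictor, in `[-1, 1]`.
#' @param r_xz Correlation between the predictors, `|r_xz| < 1`.
#' @returns The multiple correlation `R` in `[0, 1]` (square it for `R^2`).
#' @examples
#' multiple_r_two_predictors(0.66055, 0.66055, 0.25313) # 0.834
#' @export
multiple_r_two_predictors <- function(r_yx, r_yz, r_xz) {
  for (r in c(r_yx, r_yz, r_xz)) {
    if (!is.finite(r) || abs(r) > 1) {
      abort("Correlations must lie in [-1, 1].", class = "dircor_invalid_input")
    }
  }
  if (abs(r_xz) == 1) {
    abort("|r_xz| = 1: the predictors are collinear and R is undefined.",
      class = "dircor_collinear_predictors")
  }
  r2 <- (r_yx^2 + r_yz^2 - 2 * r_yx * r_yz * r_xz) / (1 - r_xz^2)
  if (r2 < -1e-10 || r2 > 1 + 1e-10) {
    abort("The correlation triple is not positive semi-definite; R is undefined.",
      class = "dircor_invalid_input")
  }
  sqrt(min(1, max(0, r2)))
}

#' All bivariate estimators for one pair of columns
#'
#' The package's one-stop verb: pull an item column and a score column out of
#' a data frame and tabulate every estimator dircor implements — pmc,
#' directional eta (both directions, plus the signed form), gamma, the three
#' Somers deltas, Kendall tau-b, Spearman rho, and the attenuation-corrected
#' `r_ac` / `e_ac`.
#'
#' @inheritParams pair_columns
#' @returns A tibble with one row per estimator (columns `estimator`,
#'   `direction`, `value`, `n`).
#' @examples
#' associate(table1(), A1, X)
#' @export
associate <- function(data, g, x) {
  pair <- pair_columns(data, {{ g }}, {{ x }})
  dplyr::bind_rows(
    pmc(pair),
    eta(pair, "g_given_X"),
    eta(pair, "X_given_g"),
    eta_signed(pair),
    gk_gamma(pair),
    somers_d(pair, "g_given_X"),
    somers_d(pair, "symmetric"),
    somers_d(pair, "X_given_g"),
    kendall_tau_b(pair),
    spearman_rho(pair),
    r_ac(pair),
    e_ac(pair))
}
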