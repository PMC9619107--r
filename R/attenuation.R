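#' Maximal and minimal product-moment correlation given the margins
#'
#' With the observed values of both variables fixed, the variances are fixed,
#' so the correlation is bounded by the covariance attainable by re-pairing
#' the values. The rearrangement inequality gives the maximum when both
#' variables are sorted into the same (ascending) order, and the minimum when
#' they are sorted into opposite orders. The sorted cross-moment is unique,
#' so tied values can be permuted freely without changing the result.
#'
#' @inheritParams pmc
#' @returns A single number: the largest (or, for `min_pmc()`, the smallest)
#'   product-moment correlation attainable with these margins.
#' @examples
#' max_pmc(pair_columns(table1(), A3, X)) # 0.759, same margins as A1
#' @export
max_pmc <- function(pair) {
  pair <- as_pair(pair)
  check_nondegenerate(pair$g, "g")
  check_nondegenerate(pair$x, "x")
  as.numeric(cor(sort(pair$g), sort(pair$x)))
}

#' @rdname max_pmc
#' @export
min_pmc <- function(pair) {
  pair <- as_pair(pair)
  check_nondegenerate(pair$g, "g")
  check_nondegenerate(pair$x, "x")
  as.numeric(cor(sort(pair$g, decreasing = TRUE), sort(pair$x)))
}

#' Maximal eta given the margins
#'
#' Eta in the `g_given_X` direction computed between independently
#' ascending-sorted copies of the two variables. For binary `g` this equals
#' [max_pmc()] exactly. For polytomous `g` the independent ordering is taken
#' as the *definition* of the maximal eta (the package logs rather than
#' asserts its optimality; see the methods vignette).
#'
#' @inheritParams pmc
#' @returns A single number in `[0, 1]`.
#' @export
max_eta <- function(pair) {
  pair <- as_pair(pair)
  sorted <- new_paired_series(sort(pair$g), sort(pair$x))
  eta(sorted, "g_given_X")$value
}

#' Attenuation-corrected product-moment correlation (R_AC)
#'
#' The observed correlation as a proportion of the maximal correlation
#' attainable with the observed margins: `r_ac = pmc / max_pmc`. A value of 1
#' means the data are already maximally co-ordered; values below 1 quantify
#' how much of the attainable association is realised. For a negative
#' observed correlation the correction is applied to the magnitude and the
#' sign reattached.
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble with `|value| <= 1`.
#' @examples
#' r_ac(pair_columns(table1(), A3, X)) # 0.117 / 0.759 = 0.154
#' @export
r_ac <- function(pair) {
  pair <- as_pair(pair)
  obs <- .pmc(pair$g, pair$x)
  mx <- max_pmc(pair)
  if (mx <= 0) {
    abort("Maximal correlation is not positive: R_AC is undefined.",
      class = "dircor_undefined_correction")
  }
  new_estimate(sign(obs) * min(1, abs(obs) / mx), "r_ac", "not_applicable",
    nrow(pair))
}

#' Attenuation-corrected eta (E_AC)
#'
#' Observed `eta(pair, "g_given_X")` divided by [max_eta()]. For binary `g`,
#' `e_ac` equals `|r_ac|`. The corrected explained proportion is simply
#' `e_ac^2`, reported alongside in [deflation_report()].
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble.
#' @export
e_ac <- function(pair) {
  pair <- as_pair(pair)
  obs <- eta(pair, "g_given_X")$value
  mx <- max_eta(pair)
  if (mx <= 0) {
    abort("Maximal eta is zero: E_AC is undefined.",
      class = "dircor_undefined_correction")
  }
  new_estimate(min(1, obs / mx), "e_ac", "g_given_X", nrow(pair))
}

#' Deflation of an observed correlation against its corrected value
#'
#' The fraction of the attainable correlation lost to mechanical deflation:
#' `(corrected - observed) / corrected` on magnitudes. With observed 0.473
#' and corrected 0.586 the deflation is 0.193, i.e. 19.3%.
#'
#' @param observed,corrected Correlation magnitudes, `|corrected| > 0`.
#' @returns A fraction in `[0, 1)` when `|observed| <= |corrected|`.
#' @export
deflation_fraction <- function(observed, corrected) {
  if (corrected == 0) {
    abort("Corrected value is zero: deflation is undefined.",
      class = "dircor_undefined_correction")
  }
  (abs(corrected) - abs(observed)) / abs(corrected)
}

#' Deflation report for a paired series
#'
#' Tabulates every observed estimator (pmc, both etas, gamma, the three
#' Somers deltas, tau-b, Spearman rho) next to the margin-corrected
#' quantities (max_pmc, max_eta, r_ac, e_ac, e_ac^2) and the resulting
#' deflation fraction of pmc relative to r_ac. This is the package's
#' benchmark view: estimators that can reach 1 on deterministic data (gamma,
#' Somers delta g-given-X, r_ac, e_ac) expose how much the pmc-family
#' estimates are mechanically depressed by scale discrepancy.
#'
#' @inheritParams pmc
#' @returns An object of class `deflation_report`: a list with tibbles
#'   `observed` and `corrected`, plus `deflation_percent` (a fraction) and
#'   `n`. `tidy()` stacks the two tibbles with a `role` column; `glance()`
#'   returns the headline one-row summary; `autoplot()` draws the estimator
#'   comparison.
#' @examples
#' deflation_report(pair_columns(table1(), A3, X))
#' @export
deflation_report <- function(pair) {
  pair <- as_pair(pair)
  observed <- dplyr::bind_rows(
    pmc(pair),
    eta(pair, "g_given_X"),
    eta(pair, "X_given_g"),
    gk_gamma(pair),
    somers_d(pair, "g_given_X"),
    somers_d(pair, "symmetric"),
    somers_d(pair, "X_given_g"),
    kendall_tau_b(pair),
    spearman_rho(pair))
  rac <- r_ac(pair)
  eac <- e_ac(pair)
  corrected <- dplyr::bind_rows(
    new_estimate(max_pmc(pair), "max_pmc", "not_applicable", nrow(pair)),
    new_estimate(max_eta(pair), "max_eta", "g_given_X", nrow(pair)),
    rac,
    eac,
    new_estimate(eac$value^2, "e_ac_squared", "g_given_X", nrow(pair)))
  structure(
    list(observed = observed, corrected = corrected,
      deflation_percent = deflation_fraction(
        observed$value[observed$estimator == "pmc"], rac$value),
      n = nrow(pair)),
    class = "deflation_report")
}

#' @export
print.deflation_report <- function(x, ...) {
  cat(sprintf("<deflation_report: n = %d>\n", x$n))
  fmt <- function(tb) {
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("  %-14s %-12s %8.3f\n", tb$estimator[i], tb$direction[i],
        tb$value[i]))
    }
  }
  cat("observed:\n"); fmt(x$observed)
  cat("corrected:\n"); fmt(x$corrected)
  cat(sprintf("deflation of pmc vs r_ac: %.1f%%\n", 100 * x$deflation_percent))
  invisible(x)
}

#' @rdname deflation_report
#' @param x A `deflation_report`.
#' @param ... Unused.
#' @export
tidy.deflation_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$observed, role = "observed"),
    dplyr::mutate(x$corrected, role = "corrected"))
}

#' @rdname deflation_report
#' @export
glance.deflation_report <- function(x, ...) {
  val <- function(tb, est) tb$value[match(est, tb$estimator)]
  tibble(
    pmc = val(x$observed, "pmc"),
    eta1 = x$observed$value[x$observed$estimator == "eta" &
      x$observed$direction == "g_given_X"],
    eta2 = x$observed$value[x$observed$estimator == "eta" &
      x$observed$direction == "X_given_g"],
    max_pmc = val(x$corrected, "max_pmc"),
    r_ac = val(x$corrected, "r_ac"),
    e_ac = val(x$corrected, "e_ac"),
    deflation_percent = x$deflation_percent,
    n = x$n)
}
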