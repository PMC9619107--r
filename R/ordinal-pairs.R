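# Classify all unordered observation pairs via the R x C contingency table.
# For each cell, pairs concordant with it live in cells with strictly larger
# row and column index; 2-D suffix sums give those counts in O(RC).
.pair_counts <- function(g, x) {
  tab <- table(factor(g, levels = sort(unique(g))),
               factor(x, levels = sort(unique(x))))
  M <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  n <- sum(M)
  R <- nrow(M); C <- ncol(M)
  # P[r + 1, c + 1] = sum(M[1:r, 1:c]), zero-padded on the first row/column
  P <- matrix(0, R + 1, C + 1)
  cs <- matrix(apply(M, 2, cumsum), R, C) # guard against dropped dims at R or C = 1
  P[-1, -1] <- matrix(t(apply(cs, 1, cumsum)), R, C)
  rows_le <- P[2:(R + 1), C + 1]                      # rows <= r, any col
  cols_le <- matrix(P[R + 1, 2:(C + 1)], R, C, byrow = TRUE)
  GG <- n - rows_le - cols_le + P[2:(R + 1), 2:(C + 1), drop = FALSE]
  GL <- matrix(P[R + 1, 1:C], R, C, byrow = TRUE) - P[2:(R + 1), 1:C, drop = FALSE]
  concordant <- sum(M * GG) # each concordant pair counted once, from its lower cell
  discordant <- sum(M * GL)
  tied_both <- sum(choose(M, 2))
  tied_g <- sum(choose(rowSums(M), 2)) - tied_both
  tied_x <- sum(choose(colSums(M), 2)) - tied_both
  list(concordant = concordant, discordant = discordant,
    tied_g_only = tied_g, tied_X_only = tied_x, tied_both = tied_both,
    total_pairs = n * (n - 1) / 2)
}

#' Pair-class tallies
#'
#' Classifies all `n(n-1)/2` unordered observation pairs of a paired series
#' as concordant, discordant, tied on `g` only, tied on `x` only, or tied on
#' both. These five tallies are the backbone of [gk_gamma()], [somers_d()]
#' and [kendall_tau_b()]. Computed from the contingency table of the pair in
#' `O(R*C)` after tabulation; tests pin the result to an exhaustive
#' quadratic enumeration.
#'
#' @inheritParams pmc
#' @returns A one-row tibble of class `pair_counts` with columns
#'   `concordant`, `discordant`, `tied_g_only`, `tied_X_only`, `tied_both`,
#'   `total_pairs`.
#' @examples
#' pair_counts(pair_columns(table1(), A1, X))
#' @export
pair_counts <- function(pair) {
  pair <- as_pair(pair)
  pc <- .pair_counts(pair$g, pair$x)
  out <- as_tibble(pc)
  class(out) <- c("pair_counts", class(out))
  out
}

#' Goodman-Kruskal gamma
#'
#' `(C - D) / (C + D)` over the concordant and discordant pairs, ignoring all
#' ties. Gamma reaches 1 on any deterministic monotone pattern regardless of
#' the scale discrepancy between the variables, which is why it serves as a
#' deflation-free benchmark for the product-moment correlation.
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble.
#' @export
gk_gamma <- function(pair) {
  pair <- as_pair(pair)
  pc <- .pair_counts(pair$g, pair$x)
  denom <- pc$concordant + pc$discordant
  if (denom == 0) {
    abort("All pairs are tied: gamma is undefined.",
      class = "dircor_undefined_statistic")
  }
  new_estimate((pc$concordant - pc$discordant) / denom, "gamma", "symmetric",
    nrow(pair))
}

#' Somers delta
#'
#' `(C - D)` divided by the pairs that differ on a designated variable.
#' Direction naming follows the cross-table convention used for item
#' analysis: `"g_given_X"` restricts the denominator to pairs differing on
#' the item `g` (i.e. `C + D + tied_X_only`), `"X_given_g"` to pairs
#' differing on the score `x`, and `"symmetric"` uses the mean of the two
#' denominators (so it is the harmonic mean of the two directional deltas).
#' Note that some textbooks attach the mirror-image labels; the convention
#' here is locked by the worked 20-person example in [table1()].
#'
#' @inheritParams pmc
#' @param direction `"g_given_X"`, `"X_given_g"` or `"symmetric"`.
#' @returns A one-row `association_estimate` tibble.
#' @examples
#' somers_d(pair_columns(table1(), A1, X), "symmetric") # 0.579
#' @export
somers_d <- function(pair, direction = c("g_given_X", "X_given_g", "symmetric")) {
  pair <- as_pair(pair)
  direction <- rlang::arg_match0(direction[[1]],
    c("g_given_X", "X_given_g", "symmetric"))
  pc <- .pair_counts(pair$g, pair$x)
  cd <- pc$concordant + pc$discordant
  denom <- switch(direction,
    g_given_X = cd + pc$tied_X_only,
    X_given_g = cd + pc$tied_g_only,
    symmetric = cd + (pc$tied_X_only + pc$tied_g_only) / 2)
  if (denom == 0) {
    abort("Zero denominator: Somers delta is undefined in this direction.",
      class = "dircor_undefined_statistic")
  }
  new_estimate((pc$concordant - pc$discordant) / denom, "somers_d", direction,
    nrow(pair))
}

#' Kendall tau-b
#'
#' `(C - D) / sqrt((C + D + T_x)(C + D + T_g))`: the signed geometric mean of
#' the two directional Somers deltas. Like the product-moment correlation it
#' cannot reach 1 when the marginals differ, so it is shown among the
#' deflation-prone estimators in [deflation_report()].
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble.
#' @export
kendall_tau_b <- function(pair) {
  pair <- as_pair(pair)
  pc <- .pair_counts(pair$g, pair$x)
  cd <- pc$concordant + pc$discordant
  d1 <- cd + pc$tied_X_only
  d2 <- cd + pc$tied_g_only
  if (d1 == 0 || d2 == 0) {
    abort("Zero denominator: tau-b is undefined.",
      class = "dircor_undefined_statistic")
  }
  new_estimate((pc$concordant - pc$discordant) / sqrt(d1 * d2), "tau_b",
    "symmetric", nrow(pair))
}

#' Spearman rank correlation
#'
#' The product-moment correlation applied to mid-ranks (average ranks for
#' ties) of both variables.
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble.
#' @export
spearman_rho <- function(pair) {
  pair <- as_pair(pair)
  rg <- rank(pair$g)
  rx <- rank(pair$x)
  if (pop_var(rg) == 0 || pop_var(rx) == 0) {
    abort("Constant ranks: Spearman rho is undefined.",
      class = "dircor_degenerate_input")
  }
  new_estimate(as.numeric(cor(rg, rx)), "spearman_rho", "symmetric", nrow(pair))
}

#' Item-rest correlation
#'
#' For an item `g` whose score `x` is a sum that includes `g` itself, the
#' item-rest correlation is `pmc(g, x - g)`: the item against the rest of the
#' test. Removes the spurious part-whole inflation of the item-score
#' correlation.
#'
#' @inheritParams pmc
#' @returns A one-row `association_estimate` tibble.
#' @export
item_rest_correlation <- function(pair) {
  pair <- as_pair(pair)
  rest <- pair$x - pair$g
  if (pop_var(rest) == 0) {
    abort("The rest score `x - g` is constant: item-rest correlation is undefined.",
      class = "dircor_degenerate_input")
  }
  check_nondegenerate(pair$g, "g")
  new_estimate(as.numeric(cor(pair$g, rest)), "item_rest", "not_applicable",
    nrow(pair))
}
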