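#' Per-item estimator table
#'
#' The workhorse of the directionality study: for every item column of a
#' person x item response matrix it records the difficulty, the population
#' item variance, the observed degrees of freedom of item and score
#' (`distinct categories - 1`), the category ratio
#' `cr_ratio = (df_x + 1) / (df_g + 1)` (how many times wider the score
#' scale is), the item-score correlation `rit`, both directions of eta
#' (`eta1` = g given X, `eta2` = X given g), and their difference
#' `diff = eta2 - eta1`. Binary items satisfy `eta1 = |rit|` exactly.
#'
#' Degenerate items (constant response) are kept as rows with `NA`
#' estimators and `flag = "degenerate"` rather than dropped, so per-bin
#' counts still add up.
#'
#' @param responses A numeric person x item matrix or data frame of item
#'   responses (non-negative integers).
#' @param score Optional score vector; defaults to the row sum of
#'   `responses`.
#' @returns A tibble with one row per item: `item`, `difficulty`,
#'   `item_variance`, `df_g`, `df_x`, `cr_ratio`, `rit`, `eta1`, `eta2`,
#'   `diff`, `flag`.
#' @examples
#' tab1 <- table1()
#' item_analysis_table(tab1[2:7], score = tab1$X)
#' @export
item_analysis_table <- function(responses, score = NULL) {
  m <- as.matrix(responses)
  if (!is.numeric(m) || nrow(m) < 2 || ncol(m) < 1) {
    abort("`responses` must be a numeric matrix with >= 2 persons.",
      class = "dircor_invalid_input")
  }
  if (is.null(score)) score <- rowSums(m)
  if (length(score) != nrow(m)) {
    abort("`score` must have one value per person.", class = "dircor_invalid_input")
  }
  items <- colnames(m)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(m)))
  df_x <- dplyr::n_distinct(score) - 1L
  score_constant <- df_x == 0L
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    g <- m[, j]
    df_g <- dplyr::n_distinct(g) - 1L
    base <- tibble(item = items[j], difficulty = difficulty(g),
      item_variance = pop_var(g), df_g = df_g, df_x = df_x,
      cr_ratio = (df_x + 1) / (df_g + 1))
    if (df_g == 0L || score_constant) {
      return(dplyr::mutate(base, rit = NA_real_, eta1 = NA_real_,
        eta2 = NA_real_, diff = NA_real_, flag = "degenerate"))
    }
    pair <- paired_series(g, score)
    e1 <- eta(pair, "g_given_X")$value
    e2 <- eta(pair, "X_given_g")$value
    dplyr::mutate(base, rit = .pmc(g, score), eta1 = e1, eta2 = e2,
      diff = e2 - e1, flag = if (e2 < e1 - 1e-9) "eta2_below_eta1" else "ok")
  })
}

#' Item table for a whole collection
#'
#' Runs [item_analysis_table()] over every test of a
#' [generate_test_collection()] result and binds the rows, joined with the
#' generating metadata.
#'
#' @param collection A `test_collection`.
#' @returns A tibble: the per-item analysis rows plus `test`, `n_persons`
#'   and the generator's `difficulty_target`, `n_categories`, `loading`.
#' @export
collection_item_table <- function(collection) {
  stopifnot(inherits(collection, "test_collection"))
  rows <- purrr::imap_dfr(collection$responses, function(m, t) {
    dplyr::mutate(item_analysis_table(m), test = t,
      item = seq_len(ncol(m)), .before = 1)
  })
  dplyr::left_join(rows, collection$meta, by = c("test", "item"))
}

#' Binned summary of the eta2 - eta1 difference
#'
#' Summarises the directionality gap `diff = eta2 - eta1` of an item table
#' across bins of either the item degrees of freedom (`df_g`) or the
#' category ratio (`cr_ratio`). Reports the per-bin mean, standard
#' deviation and count, plus a Spearman trend statistic of bin index
#' against bin mean (positive when the gap grows along the bins).
#'
#' @param rows An item table from [item_analysis_table()] or
#'   [collection_item_table()]; rows with `NA` `diff` are dropped.
#' @param by `"df_g"` (one bin per distinct value, values above
#'   `df_g_top` pooled) or `"cr_ratio"` (binned at `bin_edges`).
#' @param bin_edges For `by = "cr_ratio"`, the interior bin edges; defaults
#'   to [cr_ratio_bins_preset()]. Ignored for `df_g`.
#' @param df_g_top Pool `df_g >= df_g_top` into one top bin (default 13).
#' @returns A tibble of class `binned_summary` with columns `bin`,
#'   `bin_index`, `mean_diff`, `sd_diff`, `n`, carrying attributes
#'   `overall` (one-row tibble) and `spearman_trend`. `glance()` returns
#'   the overall row with the trend.
#' @export
binned_difference_summary <- function(rows, by = c("df_g", "cr_ratio"),
    bin_edges = NULL, df_g_top = 13L) {
  by <- rlang::arg_match(by)
  stopifnot(is.data.frame(rows), all(c("diff", by) %in% names(rows)))
  rows <- dplyr::filter(rows, !is.na(.data$diff))
  if (nrow(rows) == 0) {
    abort("No usable rows: every `diff` is missing.", class = "dircor_invalid_input")
  }
  if (by == "df_g") {
    v <- pmin(rows$df_g, df_g_top)
    lab <- ifelse(v >= df_g_top, paste0(">=", df_g_top), as.character(v))
    key <- v
  } else {
    if (is.null(bin_edges)) bin_edges <- cr_ratio_bins_preset()
    bin_edges <- sort(unique(bin_edges))
    cutv <- cut(rows$cr_ratio, breaks = c(-Inf, bin_edges, Inf), right = TRUE)
    lab <- as.character(cutv)
    key <- as.integer(cutv)
  }
  out <- tibble(bin = lab, bin_index = key, diff = rows$diff) |>
    dplyr::group_by(.data$bin, .data$bin_index) |>
    dplyr::summarise(mean_diff = mean(.data$diff), sd_diff = sd(.data$diff),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin_index) |>
    dplyr::mutate(bin_index = dplyr::row_number())
  if (nrow(out) == 0) {
    abort("Empty bin set.", class = "dircor_invalid_input")
  }
  overall <- tibble(mean_diff = mean(rows$diff), sd_diff = sd(rows$diff),
    n = nrow(rows))
  trend <- if (nrow(out) > 2) {
    suppressWarnings(as.numeric(cor(out$bin_index, out$mean_diff,
      method = "spearman")))
  } else NA_real_
  attr(out, "overall") <- overall
  attr(out, "spearman_trend") <- trend
  attr(out, "by") <- by
  class(out) <- c("binned_summary", class(out))
  out
}

#' @rdname binned_difference_summary
#' @param x A `binned_summary`.
#' @param ... Unused.
#' @export
glance.binned_summary <- function(x, ...) {
  dplyr::mutate(attr(x, "overall"), spearman_trend = attr(x, "spearman_trend"),
    by = attr(x, "by"))
}

#' Category-ratio bin edges used by the study preset
#'
#' Interior edges pooling the category ratio `C/R` into the bins used in the
#' shipped study summaries, spanning roughly equal-information groups from
#' below 2 up to above 20.
#'
#' @returns A numeric vector of interior bin edges.
#' @export
cr_ratio_bins_preset <- function() {
  c(1.929, 2.5, 3.111, 3.909, 4.333, 5, 6.833, 9.333, 10.5, 12.5, 14,
    15.5, 16.5, 18, 19, 20)
}

#' One-way ANOVA effect sizes
#'
#' Fits a one-way analysis of variance of `values` on `groups` and reports
#' the F statistic with its degrees of freedom, `eta_squared =
#' ss_between / ss_total`, and Cohen's `f = sqrt(eta^2 / (1 - eta^2))`.
#'
#' @param data A data frame.
#' @param values,groups Unquoted column names of the response and the
#'   grouping variable.
#' @returns An object of class `effect_summary`: a list with `statistic`,
#'   `df1`, `df2`, `p_value`, `eta_squared`, `cohen_f` and a `groups` tibble
#'   of per-group mean/sd/n. `tidy()` returns the group table; `glance()`
#'   the one-row summary.
#' @export
oneway_effect_sizes <- function(data, values, groups) {
  stopifnot(is.data.frame(data))
  v <- dplyr::pull(data, {{ values }})
  grp <- factor(dplyr::pull(data, {{ groups }}))
  if (nlevels(droplevels(grp)) < 2) {
    abort("Need at least two groups for a one-way analysis.",
      class = "dircor_invalid_input")
  }
  if (length(v) - nlevels(droplevels(grp)) < 1) {
    abort("Not enough residual degrees of freedom.", class = "dircor_invalid_input")
  }
  fit <- aov(v ~ grp)
  an <- anova(fit)
  ssb <- an[["Sum Sq"]][1]
  ssw <- an[["Sum Sq"]][2]
  eta2 <- ssb / (ssb + ssw)
  gtab <- tibble(group = grp, value = v) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
      sd = sd(.data$value), .groups = "drop")
  structure(list(statistic = an[["F value"]][1], df1 = an[["Df"]][1],
    df2 = an[["Df"]][2], p_value = an[["Pr(>F)"]][1], eta_squared = eta2,
    cohen_f = cohen_f_from_eta_squared(eta2), groups = gtab),
    class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, eta^2 = %.3f, Cohen's f = %.3f\n",
    x$df1, x$df2, x$statistic, x$eta_squared, x$cohen_f))
  invisible(x)
}

#' @rdname oneway_effect_sizes
#' @param x An `effect_summary`.
#' @param ... Unused.
#' @export
tidy.effect_summary <- function(x, ...) x$groups

#' @rdname oneway_effect_sizes
#' @export
glance.effect_summary <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
    p_value = x$p_value, eta_squared = x$eta_squared, cohen_f = x$cohen_f)
}

#' Convert between eta squared and Cohen's f
#'
#' `f = sqrt(eta^2 / (1 - eta^2))` and its inverse
#' `eta^2 = f^2 / (1 + f^2)`.
#'
#' @param eta_squared Proportion of variance explained, in `[0, 1)`.
#' @param cohen_f Cohen's f, `>= 0`.
#' @returns A number.
#' @examples
#' cohen_f_from_eta_squared(0.306) # 0.664
#' @export
cohen_f_from_eta_squared <- function(eta_squared) {
  if (eta_squared < 0 || eta_squared >= 1) {
    abort("`eta_squared` must lie in [0, 1).", class = "dircor_invalid_input")
  }
  sqrt(eta_squared / (1 - eta_squared))
}

#' @rdname cohen_f_from_eta_squared
#' @export
eta_squared_from_cohen_f <- function(cohen_f) {
  if (cohen_f < 0) abort("`cohen_f` must be >= 0.", class = "dircor_invalid_input")
  cohen_f^2 / (1 + cohen_f^2)
}

#' Cohen's d from a mean difference and a standard deviation
#'
#' @param mean_difference Difference of means.
#' @param sd Standardiser, `> 0`.
#' @returns `mean_difference / sd`.
#' @examples
#' cohen_d(0.025, 0.059) # 0.424
#' @export
cohen_d <- function(mean_difference, sd) {
  if (!is.finite(sd) || sd <= 0) {
    abort("`sd` must be > 0.", class = "dircor_invalid_input")
  }
  mean_difference / sd
}

#' Sidak-adjusted pairwise comparisons
#'
#' All pairwise comparisons of group means using Welch (unequal-variance)
#' two-sample t tests, with the Sidak multiplicity adjustment
#' `p_adj = 1 - (1 - p)^m` over the `m` comparisons. Groups with fewer than
#' two observations yield a flagged, undefined comparison instead of an
#' error.
#'
#' @inheritParams oneway_effect_sizes
#' @param alpha Family-wise significance level (default 0.05). The
#'   per-comparison threshold `1 - (1 - alpha)^(1/m)` is attached as the
#'   attribute `per_comparison_alpha`.
#' @returns A tibble with one row per pair: `group1`, `group2`,
#'   `mean_difference`, `statistic`, `df`, `p_value`, `p_adjusted`,
#'   `significant`, `flag`.
#' @export
sidak_pairwise <- function(data, values, groups, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  v <- dplyr::pull(data, {{ values }})
  grp <- droplevels(factor(dplyr::pull(data, {{ groups }})))
  lev <- levels(grp)
  if (length(lev) < 2) {
    abort("Need at least two groups.", class = "dircor_invalid_input")
  }
  pairs <- combn(lev, 2)
  m <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(m), function(i) {
    a <- v[grp == pairs[1, i]]
    b <- v[grp == pairs[2, i]]
    if (length(a) < 2 || length(b) < 2 || (sd(a) == 0 && sd(b) == 0)) {
      return(tibble(group1 = pairs[1, i], group2 = pairs[2, i],
        mean_difference = mean(a) - mean(b), statistic = NA_real_,
        df = NA_real_, p_value = NA_real_, flag = "undefined"))
    }
    tt <- t.test(a, b)
    tibble(group1 = pairs[1, i], group2 = pairs[2, i],
      mean_difference = mean(a) - mean(b),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, flag = "ok")
  })
  out <- dplyr::mutate(out,
    p_adjusted = pmin(1, 1 - (1 - .data$p_value)^m),
    significant = .data$p_adjusted < alpha,
    .after = "p_value")
  attr(out, "n_comparisons") <- m
  attr(out, "per_comparison_alpha") <- 1 - (1 - alpha)^(1 / m)
  out
}

#' Sidak adjustment of a raw p value
#'
#' @param p Raw p value(s) in `[0, 1]`.
#' @param m Number of comparisons in the family.
#' @returns `min(1, 1 - (1 - p)^m)`, vectorised over `p`.
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1) || m < 1) {
    abort("`p` must lie in [0, 1] and `m` >= 1.", class = "dircor_invalid_input")
  }
  pmin(1, 1 - (1 - p)^m)
}
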