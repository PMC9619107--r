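# Independent oracles and random-data generators shared across the suite.

# Exhaustive O(n^2) classification of all unordered pairs.
brute_pair_counts <- function(g, x) {
  n <- length(g)
  conc <- disc <- tg <- tx <- tb <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dg <- g[j] - g[i]
      dx <- x[j] - x[i]
      if (dg == 0 && dx == 0) tb <- tb + 1
      else if (dg == 0) tg <- tg + 1
      else if (dx == 0) tx <- tx + 1
      else if (dg * dx > 0) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  list(concordant = conc, discordant = disc, tied_g_only = tg,
    tied_X_only = tx, tied_both = tb, total_pairs = n * (n - 1) / 2)
}

# One-way ANOVA sums of squares via lm(), as an independent route to eta.
oracle_ss <- function(values, groups) {
  an <- anova(lm(values ~ factor(groups)))
  list(ss_between = an[["Sum Sq"]][1], ss_within = an[["Sum Sq"]][2])
}

# Random item/score pair with heavy ties: R item categories, scores on a
# coarse grid so tied x values are common.
random_pair <- function(n = 20, R = 2, score_levels = 8, rho = 0.6) {
  theta <- rnorm(n)
  item_latent <- rho * theta + sqrt(1 - rho^2) * rnorm(n)
  g <- as.integer(cut(item_latent, breaks = c(-Inf, sort(rnorm(R - 1)), Inf))) - 1L
  if (length(unique(g)) < 2) g[sample(n, 1)] <- (g[1] + 1L) %% R
  x <- as.numeric(as.integer(cut(theta, breaks = score_levels)))
  if (length(unique(x)) < 2) x[sample(n, 1)] <- max(x) + 1
  paired_series(g, x)
}

table1_pair <- function(item) pair_columns(table1(), {{ item }}, X)

expect_round3 <- function(actual, printed) {
  expect_equal(round(actual, 3), printed, tolerance = 1e-12)
}
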