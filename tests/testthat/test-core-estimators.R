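printed_table1 <- tibble::tribble(
  ~item, ~pmc,  ~eta1, ~eta2,
  "A1",  0.759, 0.759, 1,
  "A2",  0.721, 0.721, 1,
  "A3",  0.117, 0.117, 0.856,
  "B1",  0.747, 0.820, 1,
  "B2",  0.603, 0.606, 1,
  "B3",  0.610, 0.614, 0.985)

test_that("pmc and both eta directions reproduce the worked example", {
  t1 <- table1()
  for (i in seq_len(nrow(printed_table1))) {
    pair <- pair_columns(t1, printed_table1$item[i], X)
    expect_round3(pmc(pair)$value, printed_table1$pmc[i])
    expect_round3(eta(pair, "g_given_X")$value, printed_table1$eta1[i])
    expect_round3(eta(pair, "X_given_g")$value, printed_table1$eta2[i])
  }
})

test_that("pmc is symmetric, affine-invariant, and 1 on self-correlation", {
  x <- c(1, 3, 2, 5, 4)
  g <- c(0, 1, 0, 2, 1)
  expect_equal(pmc(paired_series(g, x))$value,
    cor(x, g)) # argument order irrelevant
  p1 <- pmc(paired_series(g, x))$value
  p2 <- pmc(paired_series(g, 10 + 3 * x))$value
  expect_equal(p1, p2)
  expect_equal(pmc(paired_series(c(0, 1, 2), c(0, 1, 2)))$value, 1)
  expect_error(pmc(paired_series(c(1, 1, 1), c(1, 2, 3))),
    class = "dircor_degenerate_input")
})

test_that("point-biserial closed form equals pmc and flips under recoding", {
  t1 <- table1()
  pair <- pair_columns(t1, A1, X)
  expect_round3(point_biserial(pair)$value, 0.759)
  expect_equal(point_biserial(pair)$value, pmc(pair)$value, tolerance = 1e-13)
  rev_pair <- paired_series(1 - pair$g, pair$x)
  expect_equal(point_biserial(rev_pair)$value, -point_biserial(pair)$value)
  expect_error(point_biserial(pair_columns(t1, B1, X)),
    class = "dircor_invalid_input")
})

test_that("binary equivalence |pmc| = eta(g|X) holds across 1000 random datasets", {
  set.seed(42)
  worst_pb <- worst_eta <- 0
  for (i in 1:1000) {
    pair <- random_pair(n = sample(10:40, 1), R = 2)
    p <- pmc(pair)$value
    worst_pb <- max(worst_pb, abs(point_biserial(pair)$value - p))
    worst_eta <- max(worst_eta, abs(abs(p) - eta(pair, "g_given_X")$value))
  }
  expect_lt(worst_pb, 1e-12)
  expect_lt(worst_eta, 1e-12)
})

test_that("|pmc| <= eta(g|X) for polytomous ordinal items (1000 datasets)", {
  set.seed(43)
  for (i in 1:1000) {
    pair <- random_pair(n = sample(12:40, 1), R = sample(3:6, 1))
    expect_lte(abs(pmc(pair)$value), eta(pair, "g_given_X")$value + 1e-12)
  }
})

test_that("eta is directional, bounded in [0, 1], and zero for one category", {
  pair <- table1_pair(B1)
  expect_false(eta(pair, "g_given_X")$value == eta(pair, "X_given_g")$value)
  one_cat <- paired_series(c(0, 0, 0), c(1, 2, 3))
  expect_equal(eta(one_cat, "g_given_X")$value, 0)
  set.seed(44)
  for (i in 1:50) {
    pair <- random_pair(n = 15, R = sample(2:5, 1))
    for (d in c("g_given_X", "X_given_g")) {
      v <- eta(pair, d)$value
      expect_true(v >= 0 && v <= 1)
    }
  }
})

test_that("eta squared is the exact square of eta and matches its reported form", {
  t1 <- table1()
  for (item in c("A1", "B1", "B2")) {
    pair <- pair_columns(t1, item, X)
    expect_equal(eta_squared(pair, "g_given_X"),
      eta(pair, "g_given_X")$value^2, tolerance = 1e-12)
  }
  # the explained proportions as reported derive from the 3-dp etas
  expect_round3(round(eta(pair_columns(t1, A1, X), "g_given_X")$value, 3)^2, 0.576)
  expect_round3(round(eta(pair_columns(t1, B1, X), "g_given_X")$value, 3)^2, 0.672)
  # perfect group separation
  expect_equal(eta_squared(paired_series(c(0, 0, 1, 1), c(1, 1, 5, 5)),
    "g_given_X"), 1)
})

test_that("ss decomposition is additive and matches the ANOVA oracle", {
  pair <- table1_pair(A3)
  dec <- ss_decomposition(pair, "X_given_g")
  expect_equal(dec$ss_total, 3.75)
  expect_equal(dec$ss_within, 1.0)
  expect_equal(dec$ss_between, 2.75)

  single <- ss_decomposition(paired_series(c(0, 0, 0), c(1, 2, 4)), "g_given_X")
  expect_equal(single$ss_between, 0)
  expect_equal(single$ss_within, single$ss_total)

  set.seed(45)
  for (i in 1:100) {
    pair <- random_pair(n = sample(10:30, 1), R = sample(2:5, 1))
    dec <- ss_decomposition(pair, "g_given_X")
    expect_equal(dec$ss_between + dec$ss_within, dec$ss_total,
      tolerance = 1e-9)
    o <- oracle_ss(pair$x, pair$g)
    expect_equal(dec$ss_between, o$ss_between, tolerance = 1e-9)
    expect_equal(dec$ss_within, o$ss_within, tolerance = 1e-9)
  }
})

test_that("signed eta carries the factual sign of the association", {
  pair <- table1_pair(A1)
  expect_round3(eta_signed(pair)$value, 0.759)
  expect_round3(eta_signed(paired_series(1 - pair$g, pair$x))$value, -0.759)
  # independent g and x: signed eta near zero
  set.seed(46)
  n <- 10000
  nullpair <- paired_series(rbinom(n, 1, 0.5), rnorm(n))
  expect_lt(abs(eta_signed(nullpair)$value), 0.05)
  # polytomous: sign borrowed from pmc
  poly <- table1_pair(B1)
  flipped <- paired_series(max(poly$g) - poly$g, poly$x)
  expect_lt(eta_signed(flipped)$value, 0)
})

test_that("two-predictor multiple R matches the closed form and an OLS oracle", {
  expect_round3(multiple_r_two_predictors(0.66055, 0.66055, 0.25313), 0.834)
  expect_equal(multiple_r_two_predictors(-0.4, 0, 0), 0.4)
  expect_error(multiple_r_two_predictors(0.5, 0.5, 1),
    class = "dircor_collinear_predictors")
  expect_error(multiple_r_two_predictors(0.9, -0.9, 0.99),
    class = "dircor_invalid_input")
  expect_error(multiple_r_two_predictors(1.2, 0, 0),
    class = "dircor_invalid_input")

  set.seed(47)
  n <- 500
  x <- rnorm(n); z <- 0.4 * x + rnorm(n)
  y <- 0.5 * x - 0.3 * z + rnorm(n)
  r_formula <- multiple_r_two_predictors(cor(y, x), cor(y, z), cor(x, z))
  r_ols <- sqrt(summary(lm(y ~ x + z))$r.squared)
  expect_equal(r_formula, r_ols, tolerance = 1e-10)
})
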