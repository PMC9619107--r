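#' Deterministic standard-normal scores
#'
#' Inverse standard-normal quantiles at `(i - 0.5) / n`, `i = 1..n`: a
#' reproducible, exactly symmetric stand-in for a sample of `n` normally
#' distributed latent values. Used as the default latent vector in the
#' discretization demos so that every reported number is deterministic.
#'
#' @param n Number of scores, `n >= 1`.
#' @returns A numeric vector of length `n` with mean zero.
#' @examples
#' normal_scores(2) # -0.674, +0.674
#' @export
normal_scores <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n %% 1 != 0) {
    abort("`n` must be a single integer >= 1.", class = "dircor_invalid_input")
  }
  qnorm((seq_len(n) - 0.5) / n)
}

#' Sample a latent trait vector
#'
#' Random counterpart of [normal_scores()]. `"normal"` draws standard
#' normals; `"skew"` draws a standardised chi-square (4 df) variate, giving
#' skewness `sqrt(2)`, to emulate a non-normal latent trait distribution.
#'
#' @param n Sample size.
#' @param distribution `"normal"` or `"skew"`.
#' @param seed Optional integer seed; when supplied, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @returns A numeric vector of length `n` with population mean 0 and
#'   variance 1.
#' @export
sample_latent <- function(n, distribution = c("normal", "skew"), seed = NULL) {
  distribution <- rlang::arg_match(distribution)
  draw <- function() {
    switch(distribution,
      normal = rnorm(n),
      skew = (rchisq(n, df = 4) - 4) / sqrt(8))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Discretization specification
#'
#' Describes how a latent vector is cut into an observed ordinal variable:
#' the number of categories, the target difficulty (mean/max of the output),
#' and the binning scheme.
#'
#' * `binary_threshold` (2 categories only): 1 for the top `p` fraction of
#'   the latent values — a binary item that a fraction `p` answers correctly.
#' * `equal_frequency`: `k` quantile bins labelled `0..k-1`; realises
#'   difficulty 0.5 regardless of `p`.
#' * `equal_width`: `k` equal-length bins over the latent range.
#' * `graded_quantile`: `k - 1` latent thresholds placed at the tail
#'   probabilities of a Binomial(`k - 1`, `p`) distribution, so the realized
#'   mean/max difficulty equals `p` up to rounding of counts; this is how
#'   the test-collection generator hits a target difficulty with a
#'   polytomous item.
#'
#' @param n_categories Integer `>= 2`.
#' @param difficulty Target difficulty in `(0, 1)`; required by
#'   `binary_threshold` and `graded_quantile`, ignored by the others.
#' @param scheme One of `"equal_frequency"`, `"equal_width"`,
#'   `"binary_threshold"`, `"graded_quantile"`.
#' @returns A list of class `discretization_spec`.
#' @export
discretization_spec <- function(n_categories, difficulty = NULL,
    scheme = c("equal_frequency", "equal_width", "binary_threshold",
      "graded_quantile")) {
  scheme <- rlang::arg_match(scheme)
  if (n_categories < 2 || n_categories %% 1 != 0) {
    abort("`n_categories` must be an integer >= 2.", class = "dircor_invalid_input")
  }
  if (scheme == "binary_threshold" && n_categories != 2) {
    abort("`binary_threshold` requires n_categories = 2.",
      class = "dircor_invalid_input")
  }
  if (scheme %in% c("binary_threshold", "graded_quantile")) {
    if (is.null(difficulty) || difficulty <= 0 || difficulty >= 1) {
      abort("This scheme needs a target `difficulty` in (0, 1).",
        class = "dircor_invalid_input")
    }
  }
  structure(list(n_categories = as.integer(n_categories),
    difficulty = difficulty, scheme = scheme), class = "discretization_spec")
}

#' Cut a latent vector into an ordinal variable
#'
#' Applies a [discretization_spec()] to a latent vector. All schemes
#' preserve the latent ordering: a larger latent value never receives a
#' smaller label, and tied latent values always share a label.
#'
#' @param latent Numeric vector, non-constant.
#' @param spec A [discretization_spec()].
#' @returns An integer vector of labels `0..k-1`.
#' @examples
#' g <- discretize_latent(normal_scores(1000),
#'   discretization_spec(2, 0.10, "binary_threshold"))
#' sum(g) # 100 ones
#' @export
discretize_latent <- function(latent, spec) {
  stopifnot(inherits(spec, "discretization_spec"))
  n <- length(latent)
  if (n < 1 || anyNA(latent) || pop_var(latent) == 0) {
    abort("`latent` must be a non-constant vector without missing values.",
      class = "dircor_invalid_input")
  }
  k <- spec$n_categories
  # ties.method = "max" keeps tied latent values in one label group
  r <- rank(latent, ties.method = "max")
  out <- switch(spec$scheme,
    binary_threshold = {
      m <- round(spec$difficulty * n)
      if (m < 1 || m >= n) {
        abort("Infeasible difficulty: p * n must round to 1..n-1.",
          class = "dircor_invalid_input")
      }
      as.integer(r > n - m)
    },
    equal_frequency = {
      u <- (rank(latent, ties.method = "average") - 0.5) / n
      pmin(k - 1L, as.integer(floor(k * u)))
    },
    equal_width = {
      w <- (max(latent) - min(latent)) / k
      pmin(k - 1L, as.integer(floor((latent - min(latent)) / w)))
    },
    graded_quantile = {
      # proportion scoring >= j follows the Binomial(k-1, p) upper tail,
      # so E[label] = (k - 1) p and the realized difficulty is ~p
      tail_p <- 1 - stats::pbinom(0:(k - 2), k - 1, spec$difficulty)
      counts <- round(tail_p * n)
      if (counts[1] < 1) {
        abort("Infeasible difficulty: no observation would leave category 0.",
          class = "dircor_invalid_input")
      }
      lab <- integer(n)
      for (j in seq_along(counts)) lab <- lab + as.integer(r > n - counts[j])
      lab
    })
  out
}

#' Identical-latent deflation demonstration
#'
#' Discretizes one shared latent vector twice — once into a narrow item `g`,
#' once into a wider score `x` — so the latent correlation is exactly 1 by
#' construction, then reports every observed and corrected estimator. With
#' the defaults (binary item with difficulty 0.10, 7-category
#' equal-frequency score, 1000 deterministic normal scores) the population
#' product-moment correlation is 0.5: the observed estimate loses half a
#' unit of correlation to scale discrepancy alone, while `r_ac`, gamma and
#' Somers delta (g given X) still detect the perfect latent ordering.
#'
#' @param n Number of latent values (used when `latent` is NULL).
#' @param item_spec,score_spec [discretization_spec()]s for the item and the
#'   score.
#' @param latent Optional latent vector; default [normal_scores(n)][normal_scores()].
#' @returns A list of class `identical_pair_demo` with elements `pair` (the
#'   [paired_series()]), `report` (the [deflation_report()]), and
#'   `latent_correlation` (always 1).
#' @examples
#' demo <- identical_pair_demo(n = 1000)
#' glance(demo$report)
#' @export
identical_pair_demo <- function(n = 1000,
    item_spec = discretization_spec(2, 0.10, "binary_threshold"),
    score_spec = discretization_spec(7, 0.50, "equal_frequency"),
    latent = NULL) {
  if (is.null(latent)) latent <- normal_scores(n)
  pair <- paired_series(discretize_latent(latent, item_spec),
    discretize_latent(latent, score_spec))
  structure(list(pair = pair, report = deflation_report(pair),
    latent_correlation = 1), class = "identical_pair_demo")
}

#' @export
print.identical_pair_demo <- function(x, ...) {
  cat("<identical_pair_demo: one latent, two discretizations, latent r = 1>\n")
  print(x$report)
  invisible(x)
}

#' Two-predictor regression deflation demonstration
#'
#' Builds three manifestations of one shared latent vector — two binary
#' items with difficulties 0.20 and 0.80 and a 7-category equal-frequency
#' score — and feeds their pairwise correlations into
#' [multiple_r_two_predictors()]. Although all three variables carry the
#' same latent information perfectly, the multiple correlation stays well
#' below 1 because each bivariate correlation is deflated by discretization.
#'
#' @param n Number of latent values, `n >= 100`.
#' @param latent Optional latent vector; default [normal_scores()].
#' @returns A list with `correlations` (tibble of the three pairwise
#'   correlations), `r` (multiple correlation) and `r_squared`.
#' @export
two_item_regression_demo <- function(n = 1000, latent = NULL) {
  if (n < 100) abort("`n` must be >= 100.", class = "dircor_invalid_input")
  if (is.null(latent)) latent <- normal_scores(n)
  g1 <- discretize_latent(latent, discretization_spec(2, 0.20, "binary_threshold"))
  g2 <- discretize_latent(latent, discretization_spec(2, 0.80, "binary_threshold"))
  x <- discretize_latent(latent, discretization_spec(7, scheme = "equal_frequency"))
  r_xg1 <- as.numeric(cor(x, g1))
  r_xg2 <- as.numeric(cor(x, g2))
  r_g1g2 <- as.numeric(cor(g1, g2))
  r <- multiple_r_two_predictors(r_xg1, r_xg2, r_g1g2)
  list(
    correlations = tibble(
      pair = c("x_g1", "x_g2", "g1_g2"),
      value = c(r_xg1, r_xg2, r_g1g2)),
    r = r, r_squared = r^2)
}

#' Specification of a synthetic test collection
#'
#' Describes a collection of simulated tests mimicking the structure of item
#' analysis datasets: each test has a number of test-takers drawn from
#' `n_persons`, a number of items in `n_items`, and items with category
#' counts, difficulties and latent loadings drawn uniformly from the given
#' ranges. Responses follow a single-factor linear latent model: item `j`
#' discretizes `lambda_j * theta + sqrt(1 - lambda_j^2) * noise` at its
#' difficulty, and the score is the row sum of the items.
#'
#' Defaults mirror typical achievement-test item banks: tests of 2-30 items,
#' 50-200 test-takers, item difficulties 0.25-0.95, category counts 2-16
#' (binary through 15-step polytomous), loadings 0.5-0.9, standard-normal
#' latent trait.
#'
#' @param n_tests Number of tests in the collection.
#' @param n_persons Integer vector of admissible test-taker counts (sampled
#'   per test).
#' @param n_items Length-2 range of items per test.
#' @param n_categories Length-2 range of item category counts (`>= 2`).
#' @param difficulty Length-2 range of target item difficulties in (0, 1).
#' @param loading Length-2 range of latent loadings in (0, 1].
#' @param latent_distribution `"normal"` or `"skew"` (see [sample_latent()]).
#' @param seed Integer seed fixing the whole collection bit-for-bit.
#' @returns A list of class `test_collection_spec`.
#' @export
test_collection_spec <- function(n_tests = 200, n_persons = c(50, 100, 200),
    n_items = c(2, 30), n_categories = c(2, 16), difficulty = c(0.25, 0.95),
    loading = c(0.5, 0.9), latent_distribution = c("normal", "skew"),
    seed = 1L) {
  latent_distribution <- rlang::arg_match(latent_distribution)
  check_range <- function(r, name, lo, hi) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      abort(sprintf("`%s` must be a non-empty range within [%s, %s].",
        name, lo, hi), class = "dircor_invalid_input")
    }
  }
  check_range(n_items, "n_items", 2, Inf)
  check_range(n_categories, "n_categories", 2, Inf)
  check_range(difficulty, "difficulty", 1e-6, 1 - 1e-6)
  check_range(loading, "loading", 1e-6, 1)
  if (length(n_persons) < 1 || any(n_persons < 10)) {
    abort("`n_persons` must list test-taker counts >= 10.",
      class = "dircor_invalid_input")
  }
  structure(list(n_tests = as.integer(n_tests), n_persons = as.integer(n_persons),
    n_items = as.integer(n_items), n_categories = as.integer(n_categories),
    difficulty = difficulty, loading = loading,
    latent_distribution = latent_distribution, seed = as.integer(seed)),
    class = "test_collection_spec")
}

#' Generate a synthetic test collection
#'
#' Realises a [test_collection_spec()]: one latent trait vector per test, a
#' discretized response per item (binary items use a threshold cut at the
#' item difficulty; polytomous items use the graded quantile scheme so the
#' realized difficulty matches the target), and the score as row sum.
#'
#' @param spec A [test_collection_spec()].
#' @returns A list of class `test_collection` with elements `responses` (a
#'   list of person x item integer matrices, one per test), `meta` (a tibble
#'   with one row per item: `test`, `item`, `n_persons`, `n_categories`,
#'   `difficulty_target`, `loading`), and `spec`.
#' @examples
#' coll <- generate_test_collection(test_collection_spec(n_tests = 3, seed = 7))
#' item_analysis_table(coll$responses[[1]])
#' @export
generate_test_collection <- function(spec) {
  stopifnot(inherits(spec, "test_collection_spec"))
  withr::with_seed(spec$seed, {
    responses <- vector("list", spec$n_tests)
    meta <- vector("list", spec$n_tests)
    for (t in seq_len(spec$n_tests)) {
      n <- sample(spec$n_persons, 1)
      k_items <- sample(seq(spec$n_items[1], spec$n_items[2]), 1)
      theta <- sample_latent(n, spec$latent_distribution)
      kcat <- sample(seq(spec$n_categories[1], spec$n_categories[2]),
        k_items, replace = TRUE)
      diff_t <- stats::runif(k_items, spec$difficulty[1], spec$difficulty[2])
      lam <- stats::runif(k_items, spec$loading[1], spec$loading[2])
      m <- matrix(0L, n, k_items,
        dimnames = list(NULL, paste0("item", seq_len(k_items))))
      for (j in seq_len(k_items)) {
        v <- lam[j] * theta + sqrt(1 - lam[j]^2) * rnorm(n)
        s <- if (kcat[j] == 2) {
          discretization_spec(2, clamp_feasible(diff_t[j], n), "binary_threshold")
        } else {
          discretization_spec(kcat[j], diff_t[j], "graded_quantile")
        }
        m[, j] <- discretize_latent(v, s)
      }
      responses[[t]] <- m
      meta[[t]] <- tibble(test = t, item = seq_len(k_items), n_persons = n,
        n_categories = kcat, difficulty_target = diff_t, loading = lam)
    }
    structure(list(responses = responses, meta = dplyr::bind_rows(meta),
      spec = spec), class = "test_collection")
  })
}

# keep round(p * n) inside 1..n-1 so a binary cut is always feasible
clamp_feasible <- function(p, n) min(max(p, 1 / n), (n - 1) / n)

#' @export
print.test_collection <- function(x, ...) {
  cat(sprintf("<test_collection: %d tests, %d items, seed %d>\n",
    length(x$responses), nrow(x$meta), x$spec$seed))
  invisible(x)
}
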