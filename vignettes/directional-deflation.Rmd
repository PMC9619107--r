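---
title: "Directionality and deflation of the product-moment correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directionality and deflation of the product-moment correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dircor)
```

## The problem

The product-moment correlation (PMC) is routinely read as a symmetric
measure: `cor(g, x)` equals `cor(x, g)`, so the variables seem
interchangeable. That reading breaks down when the two scales differ. In
item analysis — a binary or short ordinal item `g` against a much wider sum
score `x` — the PMC is numerically tied to the *directional* coefficient eta
(the correlation ratio), and only to one of its two directions: the one in
which the wide-scale variable explains the ordering of the narrow-scale
variable. Two consequences follow.

1. **Directionality.** For binary `g`, `|PMC|` equals eta in the
   `g_given_X` direction exactly (the point-biserial identity), and never
   the opposite direction. For polytomous ordinal `g`, `|PMC| <= eta1`,
   with the two close together while `eta2` can sit far above both. An
   `r^2` read off a scatterplot of such variables is therefore a
   directional quantity, whether or not the analyst intended that.

2. **Deflation.** When the scales differ, the PMC cannot reach 1 no matter
   how deterministic the association is — the attainable maximum is fixed
   by the margins. The observed estimate is thus mechanically depressed
   ("deflated"), most severely for items of extreme difficulty. This is
   distinct from classical attenuation by measurement error.

dircor implements the estimators needed to quantify both effects, a
simulator that reproduces them from a shared latent variable, and a study
pipeline that summarises the `eta2 - eta1` discrepancy across item banks.

## Estimators

All bivariate estimators act on a `paired_series`: an ordinal item `g`
(integer codes `0..R-1`) paired with a metric score `x`, validated at
construction (equal length, no missing values, ordinal coding). Population
(divide-by-`n`) moments are used throughout: the correlation itself is
invariant to the choice, but the point-biserial identity
`sd(g) = sqrt(p(1-p))` holds only in the population form, so consistency
forces it.

* `pmc()`, `point_biserial()` — the standardised covariance and its binary
  closed form `(x̄₁ - x̄₀)·sd(g)/sd(x)`; the two agree to machine precision.
* `ss_decomposition()`, `eta()`, `eta_squared()` — the between/within sum
  of squares decomposition and `eta = sqrt(SS_between/SS_total)`.
  Direction `g_given_X` (eta1) decomposes the score over the item
  categories; `X_given_g` (eta2) decomposes the item over the distinct
  score values. Additivity `SS_between + SS_within = SS_total` is asserted
  property-style on every input shape the tests generate.
* `eta_signed()` — the conventional eta is a magnitude. For binary `g` the
  factual sign is that of `x̄₁ - x̄₀`; for polytomous ordinal `g` no
  closed-form rule exists and the package attaches the sign of the PMC.
  This is a documented package convention, not an established result: for
  ordinal items the PMC and eta agree closely in magnitude and their
  co-ordering is positive whenever the association is monotone, so the PMC
  sign is the natural proxy. Nominal multi-category grouping is refused at
  construction, since a signed, order-based association is meaningless
  there.
* `pair_counts()`, `gk_gamma()`, `somers_d()`, `kendall_tau_b()` — the
  concordance family, computed from the contingency table in `O(RC)` and
  pinned by tests to an exhaustive quadratic enumeration. Direction naming
  for Somers delta follows the cross-table convention of item analysis:
  `g_given_X` divides `C - D` by the pairs *differing on the item*. Some
  textbooks attach the mirror-image labels; the convention here is locked
  by the bundled worked example (`table1()`), where `somers_d(A1, ...)`
  must give 1, 0.579 and 0.408 in the three directions.
* `spearman_rho()` (PMC on mid-ranks) and `item_rest_correlation()`
  (`pmc(g, x - g)`) complete the benchmark set.

## Attenuation correction

With the margins fixed, the covariance — hence the correlation — is
maximised when both variables are sorted into the same order (rearrangement
inequality), so `max_pmc()` is simply the PMC of the two sorted copies; the
sorted cross-moment is invariant to how ties are permuted. The
attenuation-corrected estimators divide the observed estimate by this
attainable maximum:

* `r_ac()` = `pmc / max_pmc` (sign corrected on the magnitude and
  reattached; the negative case does not arise in positively keyed item
  analysis but must not silently misbehave),
* `e_ac()` = `eta1 / max_eta`, with `max_eta()` defined as eta1 between the
  independently sorted copies. For binary `g` this coincides with
  `max_pmc` exactly. For polytomous `g` the optimality of independent
  ordering is plausible but unproven; the package treats it as the
  *definition* of the maximal eta, and the test suite counts (rather than
  asserts) empirical violations across thousands of randomized datasets —
  none have been observed, but a counterexample would be reported as a
  message, not an error.

`deflation_report()` assembles all observed and corrected estimators plus
`deflation_percent = (|r_ac| - |pmc|) / |r_ac|`, the fraction of the
attainable correlation lost. On the bundled A1 item this is 0.241: the
data are perfectly co-ordered (`r_ac = 1`) yet the PMC is stuck at 0.759
purely because a binary scale is paired with a 17-valued score.

## The simulator

`identical_pair_demo()` makes the deflation mechanism exact: one latent
vector is discretized twice, so the latent correlation is 1 by
construction, and everything lost is lost to discretization. The default
latent is `normal_scores(n)` — inverse-normal quantiles at `(i-0.5)/n` —
rather than a random draw, so the demonstration is deterministic and
exactly symmetric. The default condition is a binary item with difficulty
0.10 against a 7-category equal-frequency score on `n = 1000`: the
population PMC there is analytically 0.5 (covariance 0.3 against
`sd(g) = 0.3`, `sd(x) = 2`), i.e. half a unit of correlation lost, while
`r_ac`, gamma and Somers delta (g given X) still detect the perfect latent
ordering. Equal-frequency binning is the default score scheme because it
realises difficulty 0.5 exactly.

`generate_test_collection()` emulates an item-analysis dataset: per test, a
latent trait `theta` per person; per item, a loading `lambda`, a category
count and a target difficulty; responses discretize
`lambda*theta + sqrt(1-lambda^2)*noise`. Binary items cut at the
difficulty quantile. For polytomous items no standard recipe exists for
hitting a target mean/max difficulty, so the package places the `k-1`
thresholds at the upper-tail probabilities of a Binomial(`k-1`, `p`)
distribution: the expected label is then `(k-1)p`, so the realized
difficulty equals the target up to count rounding, and the mapping is
monotone in the latent by construction. Defaults (tests of 2-30 items,
50-200 persons, difficulties 0.25-0.95, category counts 2-16, loadings
0.5-0.9, standard-normal trait) describe a realistic mixed item bank with
mostly-narrow items, which is the regime where directionality matters.

What the simulator does *not* emulate: multidimensional traits, correlated
item residuals, guessing, and missing responses. Passing trend tests on
these collections therefore shows that the estimators behave as the theory
predicts under a clean unidimensional model — not that real item banks are
free of further complications.

## The study pipeline

`item_analysis_table()` produces one row per item (difficulty, variance,
observed `df_g` and `df_x`, the category ratio
`cr_ratio = (df_x+1)/(df_g+1)`, `rit`, `eta1`, `eta2`, `diff = eta2 -
eta1`); degenerate items are flagged rather than dropped so bin counts stay
conserved. `binned_difference_summary()` aggregates `diff` over `df_g`
values or `cr_ratio` bins (a preset of edges spanning below 2 to above 20
ships with the package) and reports a Spearman trend of bin index against
bin mean. On a seeded 200-test collection the gap falls monotonically from
binary items to 6+-category ones and rises with the category ratio — the
qualitative signature of directionality driven by scale discrepancy.
`oneway_effect_sizes()`, `cohen_d()` and `sidak_pairwise()` supply the
standard effect-size machinery; `df_x` counts *realized* score categories
(the theoretical range of a sum score is rarely exhausted at modest `n`,
and only realized categories can influence an estimate).

Šidák-adjusted post hoc comparisons use Welch (unequal-variance) t tests:
bin sizes and variances in these tables are heavily unequal, which is the
textbook indication for the Welch form.

## Numerical choices and degenerate inputs

* Printed-value comparisons use `round()` (half-even) at 3 decimals, and
  reported explained proportions are squares of 3-dp-reported etas — the
  convention under which a reported eta of 0.759 yields 0.576.
* Constant variables raise classed errors (`dircor_degenerate_input`)
  rather than returning 0; a silent zero would be indistinguishable from
  genuine absence of association.
* All-tied pair sets make gamma and the deltas undefined
  (`dircor_undefined_statistic`), again an error rather than a sentinel.
* Ties: mid-ranks for Spearman; tied latent values always share a
  discretization label; pair counting is over unordered pairs with no
  continuity corrections.
* Tolerances: algebraic identities are asserted at `1e-12`; SS additivity
  at `1e-9` relative; stochastic checks use bounds of at least five
  standard errors.

## Problem sizes

The shipped checks use the 20-person worked dataset for all exact values,
`n = 1000` deterministic normal scores for the analytic demos, property
suites of 1000 randomized datasets per invariant (n between 8 and 40,
heavy ties), and a 200-test synthetic collection (roughly 3000 items) for
the trend recovery — sizes at which every number is reproducible on a
single CPU in a few minutes while leaving the stochastic checks enough
resolution to fail visibly if an estimator is wrong.

## Known limitations

* The polytomous sign rule for `eta_signed()` and the independent-ordering
  definition of `max_eta()` are package conventions (see above), not
  theorems.
* Somers delta direction labels follow the item-analysis cross-table
  convention; users coming from other software should check the mapping
  against `table1()` before comparing outputs.
* The two-predictor multiple correlation is the closed form only; general
  multiple regression belongs to `lm()`.
* No latent-correlation estimators (polychoric, biserial) and no
  asymptotic standard errors for the concordance family are provided.
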