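---
title: "Estimating biomass conversion and expansion factors: methods and design"
author: "bcef package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biomass conversion and expansion factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcef)
```

## The model

A biomass conversion and expansion factor (BCEF) converts stem volume
$V$ (m^3^), the quantity forest inventories actually deliver, into tree
component dry biomass $W$ (Mg):

$$\hat W = \mathrm{BCEF} \times V.$$

This is a regression through the origin (RTO) of $W$ on $V$: the BCEF is a
slope. National greenhouse-gas inventories traditionally compute that slope
as a *ratio* of observed biomass to volume rather than by least squares, so
the residual sum of squares is not minimised and the biomass is, strictly,
never modelled. This package implements both families so they can be scored
against each other on any dataset:

* **Ratio estimators** — the mean of per-tree ratios
  $\frac{1}{n}\sum W_i/V_i$ (default) or the ratio of totals
  $\sum W_i / \sum V_i$. The choice matters: the two are the weighted
  least-squares RTO slopes with weights $1/V^2$ and $1/V$ respectively, so
  they respond very differently to small trees.
* **Least-squares RTO** — $\hat\beta = \sum W_iV_i / \sum V_i^2$, residual
  variance on $n-1$ degrees of freedom, $SE(\hat\beta) =
  \hat\sigma/\sqrt{\sum V_i^2}$.
* **Gamma GLM RTO** — the fallback when residual normality fails: Gamma
  family with identity link, keeping the proportional mean
  $E[W] = \beta V$ while letting the variance grow with the mean, which is
  the natural shape for positive, right-skewed biomass. Family and link are
  arguments; the identity link is the default because it preserves the
  Mg m^-3^ interpretation of the slope.

`fit_bcef_auto()` wires the gate: fit by least squares, Shapiro–Wilk the
residuals, refit with the GLM when $p < \alpha$ (default 0.05). The gate
tests *residuals of the ordinary fit*, not raw biomass — raw biomass is
almost never normal across a size-spanning sample, and it is the residual
distribution that the Gaussian machinery assumes. A raw-biomass test is
still available through `shapiro_wilk()` directly.

## The score card

Each fit is scored on six quantities (`score_fit()`):

* **AIC**, full Gaussian log-likelihood convention
  $n\log(2\pi\hat\sigma^2) + n + 2k$ with $\hat\sigma^2 = RSS/n$ and
  $k = 2$ (slope + variance). The ratio estimators are not
  likelihood-fitted; they are scored with the Gaussian likelihood evaluated
  at their slope, so both families pay the same penalty and differ only
  through their residual sums of squares.
* **SE%**, $100\,SE/\widehat{\mathrm{BCEF}}$. Note an algebraic fact worth
  knowing when reading published comparisons: the mean-of-ratios SE%
  ($100\,sd(r)/(\bar r\sqrt n)$) cannot exceed $100\sqrt{(n-1)/n}\%$ for
  nonnegative ratios, while the ratio-of-means SE can — very large printed
  ratio SE percentages therefore point at the ratio-of-means convention or
  another formula altogether.
* **CVr%**, residual standard error over mean observed biomass,
  $100\sqrt{RSS/(n-1)}/\bar W$.
* **Furnival's index**, RMSE divided by the geometric mean of the response
  transform derivative; with the identity transform (the only one these
  proportional models use) it *is* the RMSE. It exists in the score card so
  fits on transformed responses remain comparable.
* **MEP**, the mean quadratic error of prediction
  $\frac{1}{n}\sum e_i^2/(1-H_{ii})^2$. For a linear smoother this equals
  PRESS/$n$, the mean squared leave-one-out prediction error, without any
  refitting.
* **MPE**, K-fold cross-validated root mean squared prediction error
  (K = 10, seeded shuffle, pooled over all held-out trees; mean absolute
  error by option; leave-one-out fallback below n = K).

All three point estimators are one-parameter linear smoothers, with hat
diagonals $V_i^2/\sum V^2$ (LS), $1/n$ (mean of ratios) and $V_i/\sum V$
(ratio of means); each sums to one.

### Which hat goes into MEP?

Two defensible conventions exist. Using each estimator's *own* smoother hat
makes MEP exactly that estimator's PRESS/$n$ — the package verifies this
identity against explicit leave-one-out refitting. Using the RTO
*projection-matrix* hat ($V_i^2/\sum V^2$) for both methods scores them
against the same leverage structure, i.e. asks "how well does this slope
predict, given the design of the through-origin model both claim to fit?".
Published BCEF comparisons of this kind report ratio-fit MEP values several
times larger than $RSS/n$, which is impossible under the $1/n$ own-hat
(maximum inflation $(1-1/n)^{-2}$) and consistent only with the projection
hat. `compare_methods()` therefore defaults to the shared projection hat
(`hat_source = "ls"`), with `"own"` available; `mep()` and
`hat_diagonal()` are convention-free building blocks.

## Diagnostics

* `intercept_zero_test()` fits the unconstrained line
  $W = \alpha + \beta V + \varepsilon$ and t-tests $H_0: \alpha = 0$ on
  $n-2$ df. A non-rejected zero intercept is the standard justification for
  constraining the regression through the origin; a clearly positive
  intercept warns that the RTO slope — and even more so the ratio
  estimators — will be biased.
* `confidence_interval()` builds $\widehat{\mathrm{BCEF}} \pm t_{n-2} SE$
  for *every* method. The $n-2$ degrees of freedom follow the display
  convention of published BCEF error bars; the through-origin fits
  themselves use $n-1$ residual df for $\hat\sigma^2$, so for them the
  interval is mildly conservative. This deliberate mismatch is confined to
  the interval and documented here.
* `qq_points()` returns normal Q–Q coordinates at plotting positions
  $(i-0.5)/n$ — data only, no graphics.

## The synthetic populations

`generate_population()` draws stem volumes from a lognormal truncated to
$[v_{\min}, v_{\max}]$ (inverse-CDF sampling, no rejection) and builds the
three primitive components as
$W = \beta_c V + \varepsilon_c + \alpha_c$, deriving crown and AGB by
additivity so those identities hold exactly in every generated table.
Negative draws are resampled, never clipped — clipping would put a point
mass at zero biomass; the resample count is recorded. Noise models:
homoscedastic additive, additive with $sd \propto V^\gamma$, and
mean-corrected multiplicative lognormal.

`miombo_mopane_scenario()` encodes the four-species study layout this
package is designed around (Colophospermum mopane from Mopane woodland;
Afzelia quanzensis, Millettia stuhlmannii and Pterocarpus angolensis from
Miombo woodland; n = 17, 24, 15, 19). Its parameters come from the
published summary tables, chosen once:

* **Volume distribution** — for each species, `sdlog` (capped at 3) and
  `meanlog` are calibrated so the truncated-lognormal mean equals the
  published mean volume exactly (root-solve) and the expected sample
  extremes — the $1/(n+1)$ and $n/(n+1)$ truncated quantiles — sit as close
  as possible to the published min/max. Matching the mean alone leaves the
  small-tree end of the range empty, and small trees are precisely what
  separates the estimator families.
* **Biomass structure** — the published per-component two-parameter fits
  $W = \hat\alpha + \hat\beta V$ supply the slope (`true_bcef`) and the
  intercept shift per component. These printed pairs are internally
  additive across components and reproduce the published mean component
  masses at the mean volume (e.g. $0.1835 + 0.2934 \times 3.11 = 1.095$ Mg
  for the C. mopane stem), so they are the most complete printed
  description of the joint biomass–volume structure available. A strictly
  proportional population would contradict the published tables, whose
  ratio-based BCEFs run roughly twice the LS-based ones.
* **Noise** — additive heteroscedastic with $sd = c\sqrt V$ and $c$ set so
  the residual CV at the mean-volume tree is about 45% of the mean
  component mass, consistent with the published residual CVs (22–65%).
  The exponent 1/2 (variance $\propto V$) rather than 1 (variance
  $\propto V^2$) reflects the very large published ratio-estimator
  standard errors: under variance $\propto V^2$ per-tree ratios would be
  homoscedastic and those SEs could not arise.

What the generator does *not* emulate: measurement error in volume itself,
between-site differences, crown architecture, or any DBH–height allometry
(the DBH and height columns are filled from crude monotone maps of volume
for schema completeness only). Passing simulation tests therefore show the
estimators and metrics behave as the theory says on populations with this
structure — not that any particular field dataset satisfies it.

## Numerical choices and degenerate inputs

* Masses are Mg everywhere downstream of I/O; files carry kg. All BCEFs
  are Mg m^-3^.
* Hohenadl sectional volume requires exactly five equal-length segments
  (relative tolerance 1e-6) with positive mid-diameters; the stump is not
  part of the stem.
* $W_i = 0$ (a leaf-off tree) is legal for the LS and ratio estimators,
  illegal for the Gamma GLM; the auto gate keeps the LS fit in that case.
* Perfect fits: zero residuals give SE 0, degenerate confidence intervals,
  MEP/MPE 0, and an undefined Gaussian AIC (`aic_gaussian()` errors;
  `score_fit()` reports `-Inf` so noiseless pipelines still run).
* Percentage reductions between methods use $|m_{ratio}|$ as denominator —
  the only definition that stays meaningful for negative AICs. Reductions
  are reported signed, with all-pairs and positive-only summaries, because
  the ratio estimator does occasionally win a cell.
* The biomass-difference summary reports the maximum Mg-per-100 m^3^ gap
  together with the percentage *of that same pair*; the global maximum
  percentage (typically attained by a tiny-biomass component) is reported
  separately.
* K-fold folds come from a seeded shuffle into near-equal blocks; the MPE
  is invariant to fold relabelling by construction.

## Problem sizes used by the test suite

The suite verifies the MEP ≡ PRESS/$n$ identity by brute-force refitting on
100 random instances (n = 3–12) for each estimator; slope/SE agreement with
the generic linear-model solver to 1e-10; CI coverage and slope
unbiasedness with 2000 replicates at n = 30; intercept-test size and power
with 1000 replicates at n = 50 and 100; and the scenario comparison on one
seeded 75-tree population. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping the full suite around
ten seconds.

## Known limitations

* The ratio-estimator SE convention in published tables is ambiguous; both
  variants are provided and the mean-of-ratios default is a package choice,
  switchable per call.
* Furnival's index is implemented in its standard RMSE-based form; printed
  FI values in the motivating comparisons cannot be reconciled with any
  RMSE-based convention and are treated as opaque.
* The Gamma GLM's family/link for non-normal components is not pinned down
  by the published record; Gamma(identity) is a defensible default, not a
  reconstruction.
* The scenario matches printed *summaries*; the true joint distribution of
  the original 75 trees is unknowable from them.
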