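---
title: "Sensitivity analyses for two-sample Mendelian randomization: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity analyses for two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsens)
```

## The model

Each genetic variant $j$ contributes two independently estimated summary
associations: $\hat\beta_{Xj}$ (with the exposure, standard error
$\sigma_{Xj}$) and $\hat\beta_{Yj}$ (with the outcome, standard error
$\sigma_{Yj}$), taken from non-overlapping samples so the two sampling
errors are independent. If variant $j$ is a valid instrument and effects
are linear and homogeneous, the ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates one common causal
effect $\theta$. Every method in the package is a different way of pooling
the $\hat\theta_j$ — or of asking whether they are poolable at all:

* the IVW estimate is the precision-weighted mean (equivalently the
  weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
  origin with weights $\sigma_{Yj}^{-2}$) and is the efficient choice when
  **all** variants are valid;
* Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$ measures
  their mutual compatibility, with per-variant contributions $q_j$
  localising the incompatibility;
* Egger regression adds an intercept to the weighted regression: under
  InSIDE (direct effects independent of instrument strength) the intercept
  is the average pleiotropic effect and the slope remains a consistent
  estimate of $\theta$ even if every variant is pleiotropic;
* the simple and weighted medians are consistent when valid variants carry
  more than half the count (respectively, weight);
* multivariable IVW regresses $\hat\beta_{Yj}$ on associations with
  several exposures jointly, absorbing pleiotropy that acts through a
  measured trait.

Orientation is applied before any estimation: variants with
$\hat\beta_{Xj} < 0$ have all their association signs flipped jointly
(equivalent to counting the other allele), which makes every estimate
invariant to the arbitrary allele coding. A variant with
$\hat\beta_{Xj} = 0$ exactly has no defined orientation or ratio and is an
error rather than being dropped silently — silent exclusion would change
$J$ and every downstream degree of freedom. The CLI offers
`--drop-null-instruments` for explicit, logged dropping.

## Parameters that matter

* **`model` (`"fixed"` / `"random"`)** — the multiplicative random-effects
  model keeps the fixed-effect point estimate and inflates standard errors
  by $\sqrt{\phi}$, $\phi = \max(1, Q_{resid}/df_{resid})$ ($df = J-1$ for
  IVW, $J-2$ for Egger, $J-K$ for multivariable IVW). $\phi$ is truncated
  below at 1 so the random model is never anti-conservative relative to the
  fixed one; the truncation is a convention of multiplicative-dispersion
  meta-regression rather than a mathematical necessity.
* **`se_method` (`"first"` / `"second"`)** — the default first-order ratio
  SE $\sigma_{Yj}/\hat\beta_{Xj}$ ignores exposure-side sampling error but
  makes IVW-of-ratios *exactly* equal to the through-origin weighted
  regression, an identity the test suite asserts to 1e-10. The
  second-order SE
  $\sqrt{\sigma_{Yj}^2/\hat\beta_{Xj}^2 + \hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4}$
  is available everywhere but off by default; with strong instruments the
  difference is small.
* **`n_boot` (default 1000) and `seed`** — the median estimators take
  their SE from a parametric bootstrap: associations resampled from
  $N(\hat\beta, \sigma^2)$ per variant, independently on the two sides,
  median recomputed per replicate, SE = SD over replicates, CI
  $\hat\beta \pm z \cdot SD$ (percentile CIs via `ci_type`). Inside large
  simulation studies (the validation suite and `scripts/acceptance.R`) we
  use 200 replicates per fit, a problem-size choice that leaves the SE
  estimate's own noise well below the Monte-Carlo bands used there.
* **`conf_level`** (default 0.95) propagates the matching normal quantile
  to every interval and to the 1.96-SE bars of the plot builders.
* **`threshold`** in `prune_outliers()` defaults to
  `qchisq(0.95, 1)` = 3.84: a variant whose $q_j$ exceeds the 95th
  percentile of its null distribution is omitted. Default pruning is a
  single pass (all offenders judged against the full-data $Q$
  contributions at once); the iterative mode re-fits after each removal,
  which can reveal co-outliers that mask each other but may prune more
  aggressively. Both return the removal trail.
* **`exposure_sd`** — for log-odds outcomes, `to_odds_ratio()` maps an
  estimate to $e^{\hat\beta \cdot sd}$, the odds ratio per 1-SD exposure
  increase. Scaling is applied to the *final* pooled estimate, not to the
  per-variant data; since the transform is a fixed monotone function the
  order of operations only affects presentation, and doing it last keeps
  all methods on one common internal scale.

## Inference conventions

Confidence intervals and p-values are normal-approximation throughout, so
methods are comparable; `mr_egger(..., ci_dist = "t")` switches Egger to
$t_{J-2}$ inference. One deliberate exception:
`directional_pleiotropy_test()` defaults to the random-effects model with
$t_{J-2}$ inference, because with multiplicative dispersion estimated from
the weighted residuals the intercept test *is* a weighted-least-squares
t-test — with normal quantiles at $J = 17$ its size would be ~0.069 rather
than 0.05 by construction ($2(1 - F_{t,15}(1.96))$). The validation suite
checks the resulting size empirically under balanced pleiotropy.

Raw p-values are reported everywhere; no multiplicity correction is
applied (reports flag significance at a user-chosen `alpha` only as a
display column).

## Numerical choices and degenerate inputs

* **Weighted median interpolation.** With estimates sorted ascending and
  normalized weights $w'_j$, the cumulative midpoints are
  $S_j = \sum_{k \le j} w'_k - w'_j/2$; the estimate interpolates linearly
  between the two $\hat\theta$ values whose $S$ bracket $1/2$, and clamps
  to the extreme estimate if $1/2$ falls outside $[S_1, S_J]$ (a variant
  carrying more than half the total weight). The anchor for correctness is
  a brute-force oracle — the median of $10^6$ discrete copies of the
  estimates in proportion to their weights — which the interpolated value
  matches to $10^{-3}$ at $J = 10^4$, where adjacent order statistics are
  ~$10^{-4}$ apart. At small $J$ the two definitions differ by design: the
  discrete median is always one of the $\hat\theta_j$, the interpolated
  one moves smoothly with the weights.
* **Ties** in $\hat\theta_j$ are broken by a stable sort on
  (estimate, variant id), so results are invariant to row permutation.
* **Egger non-identification.** All $\hat\beta_{Xj}$ equal means no spread
  in instrument strength; slope and intercept are not separately
  identified and the fit is refused with an explicit error (this also
  surfaces as a flagged — not silently dropped — failure inside subset
  analyses, where omission can create the degenerate configuration).
* **Random omission counts.** `random_subsets()` omits
  `round(J * omit_fraction)` variants, R's round-half-to-even; with
  $J = 17$ and 30% that is 5 per replicate.
* **Seeds.** Every stochastic routine takes an explicit seed and restores
  the caller's RNG state. `operating_characteristics()` gives replicate
  $r$ the seed `seed + r` (for both the data draw and, unless overridden,
  the median bootstrap), so any replicate can be regenerated in isolation.

## The simulator: what it emulates, and what it does not

`mr_sim_config()` generates summary statistics directly — not
individual-level genotypes — because every estimator consumes only summary
data. Per variant: strength $\gamma_j \sim U(\text{gamma\_range})$, direct
effect $\alpha_j$ (zero for valid variants), true outcome association
$\Gamma_j = \theta\gamma_j + \alpha_j$, and observed associations drawn
independently as $N(\gamma_j, se_X^2)$ and $N(\Gamma_j, se_Y^2)$. The
first $\lceil J \cdot \text{invalid\_fraction}\rceil$ variants are the
invalid ones, so the truth record is unambiguous. Defaults ($J = 17$,
$\gamma \in U(0.05, 0.15)$ per allele on a log-scale biomarker,
$se_X = 0.005$, $se_Y = 0.03$ log-odds) describe a large-GWAS biomarker
analysis with strong instruments (F-statistics in the hundreds). The
bundled example dataset was drawn once from this generator with balanced
pleiotropy (scale 0.06) on half the variants, chosen a priori to give the
marked heterogeneity ($E[Q] \approx 16 + 8 \cdot (0.06/0.025)^2$) with
funnel symmetry that characterises a many-variant biomarker analysis whose
instruments are not all valid.

The architectures cover the assumption space the estimators care about:
`balanced` (InSIDE holds, no directional bias), `directional` (one-signed
direct effects, InSIDE still holds — biases IVW, leaves Egger's slope
consistent), `inside_violated` (direct effects correlated with strength —
biases Egger in the direction of the correlation; note the
strength-linked component is small against its own noise, so its empirical
correlation with $\gamma$ is detected by significance, not by size).

Deliberately **not** modelled: weak instruments and winner's curse, sample
overlap between the two association sources, correlated (LD-linked)
variants, allele-frequency structure, non-linearity, effect heterogeneity
across valid instruments. Passing the validation suite therefore shows the
estimators behave as the theory says *under the stated generating model*;
it says nothing about robustness to these further real-data complications,
and with noisy exposure associations the first-order SEs make all methods
mildly susceptible to regression dilution.

## Validation problem sizes

The suite's simulation checks use: parameter recovery and test size at
$J = 50$ with 500 replicates (bands of three Monte-Carlo standard
errors); the robustness ordering under directional pleiotropy on 30% of
$J = 17$ variants with 1000 replicates; intercept-test size under
balanced pleiotropy with 1000 replicates; the weighted-median oracle on 50
datasets of $J = 10^4$; and exact algebraic identities (IVW's two forms,
Egger-through-origin = IVW, the $Q$ decomposition, the $J = 2$ closed
form) on 100 random datasets at tolerance $10^{-10}$. These sizes keep
each Monte-Carlo band honest while the whole suite runs in about a minute.

## Scope decisions

Allele harmonization is assumed done upstream: the package operates purely
on beta/SE pairs and echoes any allele columns untouched. Published tables
of pooled estimates for the motivating CRP example are not hard-coded as
expectations anywhere: the numeric surface the package stands on is its
own identities, oracles and simulations, plus the journal-hosted
per-variant table when a user supplies it. Out of scope, as they need
individual-level data or different machinery: two-stage least squares and
LIML, L1-penalized estimators, the Sargan test, likelihood-ratio
heterogeneity tests, correlated-variant generalizations, gene–environment
interaction designs, and covariate-screening workflows.
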