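# mrsens

Sensitivity analyses for two-sample Mendelian randomization with
summarized data.

Mendelian randomization (MR) uses genetic variants as instrumental
variables: if a variant is (i) associated with a modifiable risk factor,
(ii) independent of confounders, and (iii) affects the outcome only through
the risk factor, then its association with the outcome tests whether the
risk factor is causal. Modern analyses pool dozens of variants from
different gene regions using only published summary statistics — a
beta-coefficient and standard error per variant for the variant–exposure
association and, from an independent sample, for the variant–outcome
association. With many variants it is implausible that *all* are valid
instruments, so a single pooled estimate should never be taken at face
value. `mrsens` implements the standard battery of sensitivity analyses an
applied MR analyst needs, entirely from summarized data.

## Methods

With per-variant ratio estimates θ̂ⱼ = β̂_Yj / β̂_Xj, first-order standard
errors se(θ̂ⱼ) = σ_Yj / β̂_Xj and weights wⱼ = se(θ̂ⱼ)⁻²:

- **IVW** — θ̂ = Σ wⱼθ̂ⱼ / Σ wⱼ, equal to the weighted regression of β̂_Yj on
  β̂_Xj through the origin; fixed-effect se = (Σ wⱼ)^(−1/2), or
  multiplicative random-effects se inflated by √max(1, Q/(J−1)).
- **Cochran's Q** — Q = Σ wⱼ(θ̂ⱼ − θ̂_IVW)², χ²(J−1) under homogeneity, with
  I² = max(0, (Q − df)/Q) and per-variant contributions used to prune
  outliers above the χ²(1) 95th percentile (3.84).
- **Egger regression** — weighted regression of β̂_Yj on β̂_Xj *with* an
  intercept: under the InSIDE assumption the slope estimates the causal
  effect even if all variants are pleiotropic, and the intercept estimates
  the average pleiotropic effect (its test against zero is the test for
  directional pleiotropy seen as funnel-plot asymmetry).
- **Simple / weighted median** — the median of the (inverse-variance
  weighted) empirical distribution of the θ̂ⱼ; consistent when valid
  instruments carry >50% of the count (weight); parametric-bootstrap SEs.
- **Multivariable IVW** — weighted regression of β̂_Yj on associations with
  several exposures jointly, for pleiotropy acting through measured traits.
- **Subset robustness** — leave-one-out, exhaustive leave-k-out, and random
  omission of a fraction of variants, summarising the spread and sign of
  the re-estimates.
- **Simulation engine** — synthetic summary data with known truth under
  none / balanced / directional / InSIDE-violating pleiotropy, and Monte
  Carlo rejection rates, bias and RMSE for any estimator.

For a binary outcome, estimates on the log-odds scale are rescaled to an
odds ratio per 1-SD exposure increase with `to_odds_ratio()`.

## Worked example

The package ships a **synthetic** 17-variant dataset,
`inst/extdata/crp_cad_synthetic.csv`, generated by its own simulator to
emulate a CRP → coronary-artery-disease analysis with genome-wide
significant variants: strong instruments, marked heterogeneity of ratio
estimates, but pleiotropy balanced around zero. (It is a labelled stand-in:
the published per-variant table it mimics is not redistributable here; a
user's own copy, saved with the canonical columns as
`inst/extdata/crp_cad_reference.csv`, is picked up by the test suite.)

```r
library(mrsens)
d <- read_mr_dataset(system.file("extdata", "crp_cad_synthetic.csv",
                                 package = "mrsens"),
                     exposure_label = "log CRP (synthetic)",
                     outcome_label = "CAD log odds (synthetic)",
                     exposure_sd = 1.05)

mr_ivw(d, model = "random")
#> Inverse-variance weighted (multiplicative random-effects), 17 variants
#>   estimate -0.01106  se 0.1291  95% CI (-0.264, 0.2419)  p 0.93174
#>   dispersion (variance inflation) 5.124

cochran_q(d)
#> Cochran's Q = 81.99 on 16 df, p = 7.2823e-11, I^2 = 80.5%

directional_pleiotropy_test(d)
#> Test for directional pleiotropy (Egger intercept, random model)
#>   intercept 0.02619  se 0.05149  95% CI (-0.08355, 0.1359)  p 0.61835

to_odds_ratio(mr_ivw(d, model = "fixed"))
#> OR per 1.05-unit (1 SD) increase: 0.988 (95% CI 0.879, 1.11)  [ivw, fixed]

leave_one_out(d)
#> Leave-one-out analysis, method = ivw: 17 subset estimates
#>   estimate range (-0.08466, 0.03741); positive 23.5%, negative 76.5%
```

Read: the ratio estimates are strongly heterogeneous (Q = 82 on 16 df,
I² = 80%), so some variants are not valid instruments and the fixed-effect
interval is too narrow — the random-effects model widens it five-fold.
There is no evidence of *directional* pleiotropy (intercept p = 0.62), and
no leave-one-out estimate escapes the null's neighbourhood: the correct
conclusion is no reliable evidence of a causal effect, which matches the
generator's truth (θ = 0 with balanced pleiotropy on half the variants).

`mr_analyze()` runs the whole battery at once and `write_mr_report()`
serialises it; a command-line wrapper with `analyze`, `heterogeneity`,
`robustness`, `plot`, `simulate` and `benchmark` subcommands is installed
at `system.file("cli", "mrsens.R", package = "mrsens")`.

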