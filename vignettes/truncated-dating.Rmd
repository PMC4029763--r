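---
title: "Dating charts from truncated gestational-age data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating charts from truncated gestational-age data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crldating)
```

## The problem

A dating chart predicts gestational age (GA, weeks) from crown-rump length
(CRL, mm). Prospective CRL studies recruit only between 9+0 and 13+6 weeks,
so the observed GA is truncated to [9, 14) weeks by design. Truncation of the
*outcome* biases a direct regression of GA on CRL: near the window edges only
one tail of the conditional GA distribution is observed, dragging the fitted
mean inward. Modelling in the other direction — CRL as a function of GA, a
*size chart* — is unaffected, because there GA is the covariate. All three
strategies in this package exploit that asymmetry.

## Distributional model and centiles

Conditional on CRL, GA is taken to be lognormal; conditional on GA, CRL is
taken to be normal. Each chart is a *mean-and-SD* model: fractional
polynomials (FP) of degree at most 2 for the conditional mean and at most 1
for the conditional SD, fitted by least squares. Centiles follow from
`mean + K * SD` on the modelled scale, exponentiated for log-scale outcomes,
with K the standard-normal quantile of the level. We use exact quantiles
(`qnorm(0.97)` = 1.880794) internally; published charts print 1.88, and all
printed-precision comparisons hold under either convention.

The SD curve is estimated by Altman's absolute-residual method: regress
`|residual| * sqrt(pi/2)` on the covariate, the scaling making the fitted
value an unbiased SD estimate under normal errors. This choice is the
standard in the reference-centile literature; the alternative (squared
residuals, giving a variance curve) is more sensitive to outliers.

FP selection is an exhaustive search — 8 degree-1 models, 36 degree-2 models
including repeated powers — compared on the Gaussian deviance `n log(RSS/n)`.
The default *closed test* at level 0.05 compares the best degree-2 model
against the straight line (3 df) and, if the line is rejected, against the
best degree-1 model (2 df); SD fits also allow a constant and test it first
(4 df against the best candidate). A `select = "deviance"` flag forces
global minimum-deviance selection instead. Ties within 1e-8 in deviance
prefer the lower degree, then the lexicographically earlier power tuple, so
selection is deterministic. Deviances are floored so numerically perfect fits
compare as ties rather than generating spurious chi-squared signals.

Covariates are used unshifted and unscaled: CRL and GA are strictly positive
in every supported range, and non-positive values are rejected rather than
shifted.

## The simulation world

`simulate_from_dating()` draws `ln GA ~ Normal(mu(CRL), sigma)` at each CRL
of a grid. The defaults are the study conditions: the published Verburg
equation (`verburg_equation()`: mean of ln GA = 1.4653 + 0.001737 CRL +
0.2313 ln CRL, sigma = 0.04590, natural logs), a 5-110 mm grid in 1 mm
steps, and 100 draws per grid value — 10,600 observations, about the number
of observations per GA day in the motivating cohort, large enough that
sampling noise does not dominate the method comparison. The default seed,
20131207, is recorded in the output metadata; every simulation function takes
an explicit integer seed and restores the caller's RNG state.

The generator emulates the *structure* of real CRL data — the nonlinear
median, multiplicative (lognormal) spread, and design truncation — but not
measurement error, digit preference, recall-based GA error, or between-centre
heterogeneity. Passing tests therefore demonstrate that the truncation
machinery recovers a known truth under the stated distributional assumptions,
not that any particular clinical data set satisfies them.

`truncate_ga()` retains rows with `9 <= GA < 14` weeks: the half-open window
encodes the clinical 9+0 to 13+6 recruitment rule (a woman at exactly 14+0
is not recruited). Truncation is idempotent and order-preserving.

## The three truncation strategies

**Approach 1 — low-end augmentation, restriction, extrapolation.** Fit the
size chart to the truncated data; simulate 100 CRL values per gestational
day from 7+0 to 8+6 weeks (`simulate_from_size()`, normal draws from the
size chart's mean/SD, non-positive draws rejected and redrawn since CRL is
physically positive); fit the dating model to the augmented data restricted
to CRL 20-65 mm; extrapolate the fitted mean and SD beyond. The 65 mm
ceiling is the smallest CRL seen at the 14-week bound (above it the upper GA
tail is missing); the 20 mm floor is the best-performing lower cutoff in the
`sensitivity_lower_cutoff()` analysis over {10, 15, 20} mm. Day grids are
integer days, 49-62 inclusive; the augmentation windows were published only
as "between 7 and 9" and "between 14 and 17" weeks, so the endpoint
convention (closed day grids) is ours and is configurable.

**Approach 2 — two-sided augmentation.** The same, but simulating below
(days 49-62) *and* above (days 98-119) the window and fitting the dating
model to the full augmented set — observed rows plus both blocks — with no
CRL restriction.

**Approach 3 — axis interchange.** Evaluate the size chart's 3rd, 50th and
97th CRL centiles on a daily GA grid (days 49-119 by default, matching the
augmentation resolution; the original grid was never stated) and treat each
centile as a set of (CRL, GA) coordinates. Regressing ln GA on FP functions
of CRL within each set gives three curves; note the *low* CRL centile
becomes the *high* GA centile after the interchange. The median regression
is the dating median. `recover_sd_from_centiles()` turns the outer curves
into an SD: on the log scale each outer centile is offset K standard
deviations from the median, so the two half-spreads each estimate the SD and
are averaged, then summarised by an FP regression (degree at most 1, the
observed shape of SD curves here). The outer-centile regressions use the
same FP search as the median.

## Plausibility-constrained selection

Every strategy extrapolates a fitted curve beyond its data: the size chart
down to 7 and up to 17 weeks, the restricted dating fit out to 100 mm. FP
models extrapolate well *when the selected powers behave*, but candidates
that are statistically indistinguishable on the fitted range can diverge
wildly outside it — a best-deviance size fit on GA in [9, 14) is frequently
non-monotone below 9 weeks, or pairs with an SD curve that collapses or goes
negative there, which would make augmentation draws or axis interchange
meaningless. We therefore operationalise the plausibility check that
motivated the 7- and 17-week extrapolation limits in the first place:
candidates destined for extrapolation must, over the declared range, have a
strictly increasing (and, for CRL, positive) mean, a positive SD, and
strictly increasing, positive outer centiles at K = 1.88. Mean and SD are
screened jointly — if no SD candidate yields plausible centiles for the
selected mean, that mean is rejected and selection reruns on the remaining
candidates. A straight-line mean with constant SD always satisfies the
screen, so the procedure cannot empty the candidate set in practice. The
screen is applied over the union of the declared range and the data range,
and only when a `plausible_range` is given; plain `fit_size_model()` /
`fit_dating_model()` calls are unconstrained.

## Evaluation conventions

`compare_to_reference()` evaluates both models' 3rd/50th/97th centiles on a
reporting grid (default 10-100 mm by 5) and reports differences as
`(reference - fit) * 7` days — positive when the reference exceeds the fit.
Tables carry unrounded values; printing rounds weeks and days to 2 decimals.
`coverage_counts()` counts observations outside the fitted outer centiles;
the study driver counts them over each strategy's own *fitting* set (the
augmented and/or restricted data the centiles were estimated from), which is
the denominator convention the published counts imply, restricted to CRL
20-100 mm. `agreement_summary()` reduces a difference column over a CRL
window to its maximum absolute value and mean.

## Key tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `crl_grid`, `n_per_value` | 5-110 by 1, 100 | mm, draws | study conditions (10,600 rows) |
| `truncation_window()` | [9, 14) | weeks | clinical 9+0 to 13+6 recruitment |
| `augment_days` (low / high) | 49-62 / 98-119 | days | 7-9 and 14-17 week windows |
| `n_per_day` | 100 | draws | matches per-day density of the data |
| `restrict_crl` | [20, 65] | mm | see Approach 1 above |
| `ga_eval_days` | 49-119 | days | daily grid over 7-17 weeks |
| `alpha` | 0.05 | — | closed-test level |
| centile K | `qnorm(level)` | — | exact normal deviate; 1.88 printed |

## Numerical choices and degenerate inputs

Non-positive covariates, non-positive outcomes under a log-scale fit, fewer
than 10 observations, and constant covariates raise classed errors
(`crldating_invalid_input`, `crldating_degenerate_design`). SD models are
checked positive over their fit range at construction; centile prediction
errors if the SD is non-positive at the requested point. Centile predictions
outside a model's fit range are permitted and flagged in the
`extrapolated` attribute (and column, in comparison tables). Non-monotone
predicted centile coordinates abort the axis interchange with an
`inversion_invalid` error rather than producing a folded curve.

## Known limitations

* The restriction-and-extrapolation strategy (Approach 1) is intrinsically
  seed-sensitive: FP2 candidates for ln GA on CRL restricted to 20-65 mm
  differ by far less than sampling noise in deviance, yet by days in their
  extrapolated medians at 100 mm. Across seeds its maximum absolute median
  difference over 20-100 mm ranges from a few tenths of a day to several
  days, and the lower-cutoff sensitivity analysis shows the same instability;
  single favourable runs are not representative. Approaches 2 and 3 are
  stable across seeds (about one day maximum difference; Approach 3 with a
  consistent underestimate of roughly half a day). This ordering matches the
  qualitative conclusion that two-sided augmentation is the preferable
  strategy.
* The SD-estimation formula (scaled absolute residuals) and the inclusion of
  repeated powers in the FP search are the standard literature defaults, but
  genuinely open choices; both are isolated behind `fit_fp_sd()` and
  `fp_candidates()` if alternatives are wanted.
* The lognormal GA assumption is structural: z-score diagnostics
  (`zscores()`) will flag violations but the fitting machinery does not model
  skewness beyond the log transform (no LMS/GAMLSS-style skewness).

## Problem sizes in the test suite

Unit tests run on reduced grids (20-60 observations per grid value, coarser
CRL grids) chosen so each fit remains well conditioned; the end-to-end
checks in `test-acceptance.R` and `scripts/acceptance.R` run the full 10,600
observation study, which completes in about a second.
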