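---
title: "Interpolation-based survival extrapolation: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolation-based survival extrapolation: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survpoint)
```

## The estimation problem

Lifetime economic evaluation needs a survival curve long after trial
follow-up ends. When no model fitted to the observed data is consistent
with external milestones or clinical expectation, `survpoint` takes the
coordinates themselves as the estimand: given points $(t_i, s_i)$, find
the parameter vector $\theta$ of a chosen family for which
$S(t_i;\theta) = s_i$ exactly. With one coordinate for the exponential and
two for the two-parameter families the system is exactly determined, and
for every strictly decreasing coordinate set each family has a unique
solution:

* **Weibull, log-logistic, log-normal.** A monotone transform $g$ makes
  $g(S(t))$ linear in $\log t$ — $g(s) = \log(-\log s)$,
  $\log(1/s - 1)$ and $\Phi^{-1}(1-s)$ respectively — so the two
  parameters are the slope and intercept of the line through two
  transformed points. Strict monotonicity of the coordinates guarantees a
  positive slope, hence a valid shape (or positive `sdlog`).
* **Gompertz.** Eliminating the rate leaves a single equation for the
  shape $b$, $\frac{e^{bt_2}-1}{e^{bt_1}-1} = \frac{\log s_2}{\log s_1}$.
  The left side (defined as $t_2/t_1$ at $b=0$) is continuous and strictly
  increasing in $b$ with range $(1,\infty)$, while the right side exceeds
  1 for any decreasing pair, so a unique real root always exists. It is
  bracketed by doubling outward from $[-1, 1]$ and refined by `uniroot`
  at tolerance $10^{-14}$; a residual on the ratio above $10^{-10}$ is
  reported as non-convergence (unreachable in practice, but the guard
  keeps the contract explicit). Negative roots are legitimate and produce
  a survival plateau at $e^{a/b}$ — often exactly the behaviour an
  external long-term milestone implies.

Exactness is the package's contract: a solution is `converged` only if
every plug-back residual $|S(t_i;\hat\theta) - s_i|$ is below $10^{-8}$, a
threshold far below any decision-relevant survival difference yet
comfortably achievable in double precision. Over-determined systems (3+
points) are rejected rather than least-squares fitted: approximate fits
are a different estimand and deliberately out of scope.

## Parameterisations and numerical edges

The families use the parameterisation conventions of mainstream parametric
survival software (shape/scale for Weibull and log-logistic;
meanlog/sdlog; shape/rate for Gompertz with real-valued shape), so solved
parameters can be carried into economic models without translation.

Numerical choices worth knowing:

* Gompertz $H(t) = a\,(e^{bt}-1)/b$ switches to its series limit
  $H \approx a t$ when $|bt| < 10^{-10}$, removing the $0/0$ at the
  exponential boundary; continuity there is property-tested.
* Hazards at $t = 0$ return the mathematical limit rather than erroring
  (0 for shape > 1 and for the log-normal, the constant $1/\sigma$ at
  shape = 1, `Inf` for shape < 1), so hazard panels have a defined left
  endpoint.
* Quantiles below a Gompertz plateau or a cure fraction raise a classed
  infeasible-quantile error instead of returning `NaN`.
* Coordinate validation is strict and classed (count, ties, monotonicity,
  domain), and `solve_all()` records per-family failures without aborting
  the batch.

## Piecewise models and the unconditional-scale decision

A piecewise model follows the Kaplan-Meier estimate (computed by
`survival::survfit`, Greenwood variance, log cumulative-hazard confidence
intervals — the transformation that keeps the interval inside $[0,1]$) up
to a join time $t_0$, then a parametric tail rescaled by the anchor
$S(t_0)$. Two conventions were genuinely open:

* **Points are interpreted on the unconditional scale.** A user quoting an
  external 5-year survival of 10% means the assembled curve must pass
  through 0.10 — so $(t_i, s_i)$ is converted internally to the
  conditional coordinate $((t_i - t_0),\, s_i / S(t_0))$ before solving
  the tail. The conditional reading would make the assembled curve miss
  the quoted milestone, which defeats the purpose of anchoring on external
  evidence. Cure-model coordinates are likewise taken on the overall
  scale, for consistency.
* **The anchor is the right-continuous KM step value at $t_0$** (the value
  after a step landing exactly on $t_0$), the standard convention; fixing
  it makes the continuity test at the join well-defined. Without data an
  explicit anchor is accepted and the prefix is drawn as a straight line
  from $(0, 1)$ — a display convention only; everything from $t_0$ onward
  is unaffected.

## Background mortality

The floor substitutes the general-population hazard wherever the model
hazard falls below it:
$h_{adj}(t) = \max\{h_{model}(t),\, h_{pop}(a_0 + t/c)\}$, with the annual
probability $q_x$ converted to a hazard by $-\log(1-q_x)$, treated as
piecewise constant per year of age, and divided by the time-units-per-year
constant $c$ (years 1, months 12, weeks 52.18, days 365.25). The adjusted
survival integrates the max-hazard by the midpoint rule on 20,000 uniform
intervals over the horizon — the midpoint rule sidesteps hazards that
diverge at $t = 0$ (Weibull shape < 1) and is exact for the flat-table
case the tests verify analytically. The adjustment is applied after
solving, so specified coordinates may no longer be interpolated; this is
the documented semantics, not an accident. RMST uses the trapezoidal rule
on 10,001 points, at which refinement changes the value by under
$10^{-6}$ relative for the smooth curves involved.

## Probabilistic sensitivity analysis

The PSA treats the uncertainty of a maximum-likelihood fit to uploaded
data as a proxy for the uncertainty of the interpolated extrapolation: the
fitted variance-covariance matrix is **re-centred on the interpolated
parameters** and sampled (multivariate normal, 1,000 draws by default,
pointwise 2.5/97.5 percentiles). Two design choices were open:

* **Transformation scale.** Sampling happens on the scale on which
  standard fitters report covariance — log for strictly positive
  parameters, identity for the Gompertz shape and the log-normal meanlog —
  which keeps every draw inside the parameter domain. The exponential MLE
  has the closed form $\hat\lambda = d/T$ with
  $\mathrm{var}(\log\hat\lambda) = 1/d$; other families are optimised by
  BFGS on the transformed scale from neutral starts (rate $d/T$, shape 1),
  with the covariance from the inverse numerical Hessian.
* **What the coverage property can claim.** When the interpolated
  coordinate lies on the fitted curve (e.g. the fitted model's median),
  the band centre coincides with the MLE and the 95% band covers the true
  survival at the nominal rate — the property the test suite checks by
  repeated simulation (200 repetitions, 150 subjects each, binomial
  tolerance). When coordinates come from elsewhere — the method's whole
  point — the band is a proxy: its centre is not an estimator of anything
  the data alone identify, and nominal coverage is neither expected nor
  claimed.

For piecewise models the bootstrap variant resamples records with
replacement, rebuilds the KM prefix and anchor, re-solves the tail through
the re-anchored conditional points and draws tail parameters around that
solution, so the band reflects both the nonparametric prefix and the
parametric tail. Replicates that become degenerate (no events, no support
at $t_0$, anchor at or below a specified survival) are skipped and
counted, never silently imputed.

All randomness flows through explicit integer seeds; identical inputs and
seed give bitwise-identical draws.

## What the synthetic generator emulates — and what it does not

`simulate_event_data()` draws event times by inverse-transform sampling
through the same quantile functions the rest of the package exposes (one
tested inversion, no per-family special cases), with administrative cutoff
and independent exponential censoring. For plateau-type Gompertz models
the improper fraction $e^{a/b}$ of subjects never fails; they are censored
at the cutoff, which must then be finite — the simulator never loops
hunting for an event that cannot occur. `synthetic_life_table()` is a
Gompertz-Makeham schedule $q_x = 1 - e^{-(A + Bc^x)}$, defaults
$A = 2\times10^{-4}$, $B = 2.7\times10^{-5}$, $c = 1.1$, male hazard
scaled by 1.4 — a plausible adult schedule (female annual hazard about
$5\times10^{-4}$ at age 30, about 0.02 at 70), explicitly synthetic and
not a national table.

The generator produces independent, identically distributed,
non-informatively censored records from the *same* family later fitted or
interpolated. Real trial data violate most of this — covariate mixtures,
informative dropout, delayed treatment effects, model misspecification —
so green tests demonstrate the correctness of the machinery (solving,
assembly, uncertainty propagation), not that any family is adequate for a
given dataset. Choosing the family and the coordinates remains a clinical
and evidential judgement the package cannot make; it reports hazard
curves, RMST and residuals precisely so that judgement is informed.

## Problem sizes used by the test suite

Property suites run 500 random coordinate pairs across all five families
(interpolation exactness), 200 pairs against an independent damped-Newton
root-finding oracle, simulation checks at 150–10,000 subjects, and
1,000-draw PSA bands; the full suite and the reproduction script each run
in well under a minute on a single core. These sizes give stochastic
checks binomial headroom (assertions use 3–4 standard errors or 99%
binomial intervals) while keeping the suite fast.

## Known limitations

* Exact interpolation only: no covariates, hazard ratios, additional
  families (e.g. generalised gamma), or approximate/over-determined fits.
* No left truncation, competing risks or interval censoring in the data
  layer.
* The PSA quantifies parameter uncertainty only — structural uncertainty
  across families is the analyst's to explore (model averaging helps
  visualise it but carries no posterior weights).
* Background mortality assumes the life table covers every age the
  horizon reaches; it errors rather than extrapolating the table.
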