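---
title: "Detecting cryptic Allee effects in mussel fertilization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic Allee effects in mussel fertilization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticallee)
```

## The scientific problem

Sessile broadcast-fertilizing organisms such as freshwater mussels depend on
conspecific density for reproduction: females filter sperm from the water
column, and sperm concentration decays quickly with distance from its source.
A positive fitness–density relationship (a component Allee effect) may
therefore exist at the scale of a 0.25 m² quadrat yet be invisible in
population-level summaries, and visible locally only under flow conditions
that do not disperse sperm — a *cryptic* Allee effect. `crypticallee`
implements a two-level Bayesian binomial-logit model designed to separate
those scales, together with a synthetic study generator that reproduces the
sampling design of a two-year survey of *Margaritifera laevis* beds (14
population × year replicates, 91 gravid females) so that the whole inference
pipeline can be validated against known ground truth.

## The hierarchical model

For gravid female $i$ in population $j$ and year $t$, the number of
fertilized units $y_{i,j,t}$ out of $n = 300$ counted units is modelled as

$$y_{i,j,t} \sim \mathrm{Binomial}(n,\, p_{i,j,t}),$$

with a logit-linear predictor combining local covariates, their interactions
with local density, and three random-effect sets:

$$
\operatorname{logit}(p_{i,j,t}) = \alpha_{j,t}
 + \beta_1 \mathrm{DEN} + \beta_2 \mathrm{VEL} + \beta_3 \mathrm{DEP}
 + \beta_4 \mathrm{SUB}
 + \beta_5 \mathrm{DEN}\!\cdot\!\mathrm{VEL}
 + \beta_6 \mathrm{DEN}\!\cdot\!\mathrm{DEP}
 + \beta_7 \mathrm{DEN}\!\cdot\!\mathrm{SUB}
 + \beta_8 \mathrm{LOC} + \beta_9 \mathrm{SHELL}
 + \gamma_{k(j),t} + \varepsilon_{i,j,t},
$$

where DEN is local conspecific density (individuals / 0.25 m²), VEL current
velocity (cm s⁻¹), DEP water depth (cm), SUB substrate coarseness (1–4), LOC
distance from the upstream edge of the bed (m) and SHELL shell length (mm).
The population intercept carries the population-scale submodel:

$$
\alpha_{j,t} = \alpha_{\mathrm{global}}
 + \alpha_1 \mathrm{P\_DEN}_{j,t} + \alpha_2 \mathrm{CAT}_{j,t}
 + \alpha_3 \mathrm{P\_DEN}_{j,t}\!\cdot\!\mathrm{CAT}_{j,t}
 + \omega_{j,t},
$$

with P_DEN the mean population density (the mean of DEN over the replicate's
females) and CAT the catchment area (km²). The random effects are
$\gamma_{k(j),t} \sim N(0, \sigma^2_\gamma)$ for sampling date nested in
year, $\omega_{j,t} \sim N(0, \sigma^2_\omega)$ for the population replicate,
and an observation-level overdispersion term
$\varepsilon_{i,j,t} \sim N(0, \sigma^2_\varepsilon)$ — one latent value per
female, the standard construction for extra-binomial variation in count
regressions. Because the population-level coefficients are informed by all
females rather than only the 14 replicate means, the model retains usable
power at the population scale despite the small number of replicates.

### Priors

All 13 fixed effects get independent Normal(0, variance 100) priors —
variance, not precision, so the prior sd is 10 logit units, effectively flat
over the plausible range. Each variance component $\sigma^2$ gets a
Uniform(0, 100) prior *on the variance itself*; `prior_spec()` exposes both
constants. We read "variance of 100" literally rather than as a BUGS-style
precision; with fertilization logits spanning roughly ±5 the difference is
immaterial, but the literal reading is the reproducible one.

### Standardization

All eight covariates are z-scored (sample sd, $n-1$ denominator) before
fitting; interaction columns are products of the already-standardized main
columns, so main effects are interpretable at covariate means. Local
covariates are standardized over the 91 female rows; the two population-level
covariates over the 14 population replicates, which makes their coefficients
per population-sd rather than weighted by how many females each population
contributed. The `StandardizationSpec` (stored in the design and exportable
as a JSON sidecar) lets predictions be conditioned and axes back-transformed
in natural units.

## Posterior computation

`run_chains()` samples the joint posterior — fixed effects, variance
components and every latent effect — with componentwise adaptive random-walk
Metropolis (Metropolis-within-Gibbs), the same updating pattern BUGS uses,
implemented in compiled code with incremental likelihood updates so a
proposal only re-evaluates the records it touches. Step sizes adapt toward
an acceptance rate of 0.44 (the optimal scalar random-walk rate) in batches
during burn-in only and are frozen afterwards, preserving detailed balance
for every kept draw. Variance components are updated on the $\sigma^2$ scale
with proposals reflected at the Uniform(0, 100) bounds.

Two design choices matter for mixing:

* **Compensated recentering moves.** Intercept-like fixed effects and their
  random-effect blocks are strongly negatively correlated in the posterior
  (adding $\delta$ to $\alpha_{\mathrm{global}}$ and subtracting $\delta$
  from every $\omega_{j,t}$ leaves the likelihood untouched). The sampler
  therefore adds moves that shift a fixed effect and counter-shift the
  matching latent block along these likelihood-invariant directions — for
  population-constant design columns through $\omega$, for date-constant
  columns through $\gamma$, and for every column through the
  observation-level $\varepsilon$. Only the normal priors enter those
  Metropolis ratios, so the moves are nearly free, and they cut the worst
  split R-hat on short chains from roughly 2 to below 1.1.
* **Initial values.** Chains start from independent draws with sd 2 on the
  logit scale (`init_dispersion`), overdispersed relative to any plausible
  posterior while staying in the region where the binomial likelihood has
  usable curvature; starting from the prior's own scale (sd 10) would place
  initial logits around ±20, where the likelihood is an uninformative
  plateau. Variance components start uniformly in (0.1, 10); latents at
  N(0, 0.5).

The reference chain settings are 100 000 iterations, 20 000 burn-in and
thinning 20 (4000 kept draws per chain) with 3 chains. The validation suites
use shorter chains — documented per test below — because the compensated
moves make the reduced settings sufficient for the problem sizes involved.

### Convergence and summaries

`rhat()` implements the split-chain, rank-normalized potential scale
reduction factor: chains are halved, the pooled draws are transformed to
normal scores via their ranks, and the classic between/within variance ratio
is computed on the result; constant draws return 1 by convention. We treat
1.1 as the convergence threshold. `summarize_draws()` reports empirical
medians, central 95% credible intervals, and sign probabilities computed as
draw fractions, with draws exactly equal to zero (a measure-zero event)
counted as positive. A parameter is flagged "significant" when its 95%
interval excludes zero, the same criterion used to colour the caterpillar
plot (`autoplot()` on a fit).

## Model checking

`bayesian_p_value()` runs a posterior predictive check: for every kept draw
the discrepancy between observed counts and that draw's fitted probabilities
is compared with the same discrepancy on a replicate dataset
$y^{rep} \sim \mathrm{Binomial}(300, p)$ simulated under the draw. The
default discrepancy is the Pearson chi-square
$T = \sum_i (y_i - n p_i)^2 / (n p_i (1 - p_i))$; absolute-residual and
deviance alternatives are provided because the literature this check comes
from does not pin the statistic down. Values near 0.5 indicate adequate fit.
Fitted probabilities are clipped at $10^{-12}$ from the boundary inside the
discrepancy only, and the number of clipped values is reported.

With an observation-level random effect in the model the check is
conservative (fitted $p_i$ track $y_i$ closely), which is why calibration is
asserted as an interval, not uniformity: on well-specified synthetic data we
require the p-value to fall in (0.05, 0.95) in at least 18 of 20 replicates.

## The synthetic study generator

The generator reproduces the survey design: 10 populations sampled in the
first year (1–12 females each, one sampling date per population), four
re-sampled the next year (4–20 females, two sampling dates), 91 females in
total; transects 3–5 m apart with about two females per transect, `loc`
measured from the upstream-most transect; each female also receives a
cross-stream coordinate on an 8 m channel.

Covariate distributions are matched to the observed summary table:

* Current velocity, depth, substrate coarseness and shell length come from
  truncated normals whose *post-truncation* moments are solved numerically to
  equal the observed mean and sd (naive truncation of Normal(16.5, 14.4) at
  (0.2, 76.5) would inflate the velocity mean by ~20%). Velocity and depth
  have a site-level component (ICC 0.5): streams differ in flow regime, and
  the solver matches the *marginal* moments by Gaussian quadrature over the
  site effect. Shell length's sd is not reported in the source table; we use
  12 mm (≈ range/5).
* Local density DEN is an overdispersed count: a latent bed mean density
  $\mu_j$ from a scaled beta on (0.5, 31.8) with mean 18.4 and sd 8.5,
  then DEN ~ NegBin($\mu_j$, size 1.61) truncated to (0, 79). The latent sd
  is below the reported population-level sd of 11.0 deliberately: the
  reported value is the sd of *sample means over few quadrats*, which
  includes quadrat sampling noise; with the latent sd at 8.5 the generated
  `p_den` (derived, as in the field protocol, by averaging the replicate's
  local densities) reproduces the reported spread, while a latent sd of 11
  would force a U-shaped density distribution with almost no mid-density
  beds. The NB size recovers the observed marginal sd of 18.6.
* Catchment area is a moment-matched truncated lognormal, constant per
  population across years.

### Regression flavor

`simulate_outcomes_regression()` draws the latent effects from their normal
laws and $y$ from the exact model likelihood at user-supplied true
parameters. The default truth (`default_true_parameters()`) encodes the
qualitative structure of interest — a strong positive local density effect
(0.8) damped by velocity (−0.6) and depth (−0.35), null population-level
coefficients, moderate variance components (0.25/0.5/0.25) — and is the
ground truth for the parameter-recovery and calibration suites.

### Mechanistic flavor: the cryptic scene

`make_cryptic_dataset()` generates outcomes from physics rather than from
the model, so that fitting the model to it is a genuine test. Males sit in
each sampled female's quadrat (1:1 sex ratio, a bed strip worth 8 quadrats
of the local density). A female's exposure is a kernel sum over male groups
with exponential decay over Euclidean (along-flow × cross-stream) distance;
the decay length $\lambda = 0.5\,(1 + 2\,\mathrm{VEL}/16.5)(1 +
2\,\mathrm{DEP}/29.7)$ m grows with velocity and depth (mixing), while the
locally released sperm is simultaneously diluted by the advective water
flux, dividing exposure by $(1 + \mathrm{VEL}/8)(1 + \mathrm{DEP}/120)$.
Per-male sperm output is normalized by the bed's mean density
(filter-feeding competition for seston), so exposure tracks a female's
density *relative to her bed*; because the relative-density distribution is
(by the NB construction) nearly independent of the bed mean, population mean
density carries almost no information about population mean fertilization —
the population scale is decoupled structurally, not by tuned cancellation.
Exposure maps to fertilization probability through a Michaelis-type
saturating response with half-constant 40.

None of these constants is a measured quantity; they are deliberately
synthetic, exposed in `default_mechanistic_constants()`, and frozen after a
brute-force check at generator scale (200 populations × 25 females): the
population-scale correlation between mean density and mean fertilization
stays within ±0.2 while the local density–fertilization correlation inside
the slowest-velocity quartile exceeds 0.4. Fitting the model to a default
91-female cryptic dataset then reproduces the two-scale contrast: local
density flagged positive, density × velocity negative, population density
undetected.

### What the generator does not emulate

Hydrodynamic realism (turbulence, plume anisotropy), host-fish dynamics,
multi-year demography, measurement error in covariates, and any spatial
correlation in substrate or shell length. Passing the recovery and
calibration suites therefore shows that the inference machinery is correct
and powerful enough for this design — not that the mechanistic constants
describe real beds.

## Numerical choices

* Stable log-inverse-logit everywhere: $\log p = -\log(1 + e^{-\eta})$
  evaluated by the shifted `log1p` form, so logits up to ±700 do not
  overflow; inside likelihood evaluation $p$ is clipped at $10^{-12}$ from
  the boundary.
* The binomial coefficient is included in `log_likelihood()`, so reported
  values are absolute and comparable across implementations.
* Sample sds use the $n-1$ denominator throughout.
* Variance proposals reflect at (0, 100); a reflected value landing exactly
  on a bound is rejected.
* Truncated draws use inverse-CDF sampling (no rejection loops except the
  integer NB truncation, which resamples and finally clamps).
* Ties in sign probabilities: draws equal to zero count as positive.

## Problem sizes used by the validation suites

The test suite runs end-to-end at reduced scales chosen so the full suite
completes in a few minutes: parameter recovery uses 8 populations × 300
females with 20 000/5 000/10 chains × 3 over 5 seeds (requiring R-hat ≤ 1.1
on all 13 fixed effects and truth coverage for ≥ 12 of 13); posterior
predictive calibration uses 20 replicates of the 91-female design with
6 000/2 000/4 chains × 2; the cryptic end-to-end fit uses
30 000/10 000/10 × 3. `scripts/acceptance.R` re-runs the same pipeline from
scratch at these sizes and writes its principal quantities as JSON.

## Known limitations

* The sampler is componentwise; posteriors with strong correlations *not*
  aligned with the recentering directions (e.g. between two slope
  coefficients under heavy collinearity) mix more slowly. The correlation
  screen (`correlation_screen()`, threshold |r| < 0.5) guards the intended
  use case.
* With 14 population replicates the population-level coefficients are
  weakly identified by design; their wide intervals are a feature of the
  data structure, not a convergence failure.
* `derive_population_density()` treats re-sampled populations as separate
  (j, t) replicates, so P_DEN can differ between years for the same bed.
* The Bayesian p-value's conservatism under observation-level random
  effects means values near 0.5 should not be read as proof of fit, only as
  absence of gross misfit.
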