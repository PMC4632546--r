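# crypticallee

Hierarchical Bayesian analysis of density-dependent fertilization success in
freshwater mussels — built to detect *cryptic* component Allee effects:
positive fitness–density relationships that exist at the scale of a
0.25 m² quadrat but are masked at the population scale and by local flow
conditions.

Sessile mussels fertilize by filtering sperm from the water column, and
sperm concentration decays within metres of its source. Whether a female's
fertilization success rises with conspecific density therefore depends on
*which* density you measure (her quadrat vs. her bed's mean) and on the flow
conditions that disperse sperm (current velocity, depth, substrate,
catchment). `crypticallee` provides the full analysis pipeline for per-female
fertilization counts from such a survey, plus a synthetic study generator
with known ground truth for validating the whole chain.

## The model

For gravid female *i* in population *j*, year *t*, with *y* fertilized units
out of *n* = 300 counted:

```
y[i,j,t] ~ Binomial(n, p[i,j,t])

logit(p) = alpha[j,t]
         + b1*DEN + b2*VEL + b3*DEP + b4*SUB
         + b5*DEN*VEL + b6*DEN*DEP + b7*DEN*SUB
         + b8*LOC + b9*SHELL
         + gamma[date(j),t] + eps[i]               (local level)

alpha[j,t] = alpha_global + a1*P_DEN + a2*CAT + a3*P_DEN*CAT + omega[j,t]
                                                   (population level)
```

with `gamma ~ N(0, s2_gamma)` (sampling date nested in year),
`omega ~ N(0, s2_omega)` (population replicate) and an observation-level
overdispersion term `eps ~ N(0, s2_eps)`. Priors are Normal(0, variance 100)
on all 13 fixed effects and Uniform(0, 100) on each variance. Inference is
by an adaptive Metropolis-within-Gibbs sampler (compiled core, recentering
moves for the hierarchy), with split-chain rank-normalized R-hat, posterior
predictive Bayesian p-values, sign-probability effect tables and
percentile-conditioned prediction curves. All covariates are standardized
before fitting; interactions are products of standardized mains.

## Worked example

Simulate the mechanistic "cryptic" dataset — fertilization driven by
physical sperm dilution, not by the statistical model — at the study's
design size (14 population replicates, 91 females), fit the model, and ask
the two-scale question:

```r
library(crypticallee)

sim <- make_cryptic_dataset(seed = 1)
fit <- fit_fertilization_model(
  sim$females, sim$populations,
  config = mcmc_config(n_iterations = 30000, n_burnin = 10000,
                       thin = 10, n_chains = 3, seed = 42)
)
glance(fit)
#> # A tibble: 1 × 6
#>   n_females n_population_replicates n_chains n_draws max_rhat converged
#>       <int>                   <int>    <int>   <int>    <dbl> <lgl>
#> 1        91                      14        3    6000     1.05 TRUE

effect_table(fit)
#> # A tibble: 13 × 8
#>    parameter        level        median   lower   upper p_sign sign  significant
#>  1 alpha_global     population -0.505   -0.874  -0.174   0.997 nega… TRUE
#>  2 alpha_pden       population  0.210   -0.177   0.623   0.874 posi… FALSE
#>  3 alpha_cat        population  0.236   -0.0979  0.573   0.932 posi… FALSE
#>  4 alpha_pden_x_cat population  0.342   -0.257   0.892   0.891 posi… FALSE
#>  5 beta_den         local       0.316    0.197   0.437   1     posi… TRUE
#>  6 beta_vel         local      -0.0535  -0.163   0.0553  0.832 nega… FALSE
#>  9 beta_den_x_vel   local      -0.172   -0.276  -0.0734  1.000 nega… TRUE
#>  ...

bayesian_p_value(fit, seed = 2)
#> Posterior predictive check (pearson_chi2): Bayesian p-value = 0.471
```

The fitted model recovers the pattern the generator buried in the physics:
local density has a clearly positive effect (`beta_den`, P(>0) = 1.00,
interval excluding zero) that is damped by current velocity
(`beta_den_x_vel` negative, P(<0) > 0.999), while mean population density
(`alpha_pden`) shows nothing — its 95% interval spans zero. The Bayesian
p-value near 0.5 indicates no gross misfit. `autoplot(fit)` draws the
caterpillar plot of all 13 effects; `plot_interaction_panels(fit)` shows
predicted fertilization over density at the 25th/75th percentiles of
velocity and depth, in natural units.

For simulation with known regression-scale truth (parameter recovery,
calibration studies) use `simulate_study(study_scenario(), seed)`;
`validate_study_data()` prints record counts, covariate summaries and the
collinearity screen for any dataset in the documented CSV layout
(`read_females_csv()`, `read_populations_csv()`). `run_pipeline()` chains
validate → simulate → fit → check → report into a directory with a hashed
manifest.

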