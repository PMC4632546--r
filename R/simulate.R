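# Outcome simulation from the model's own structure, and the top-level
# simulate_study() driver.

#' Simulate fertilization outcomes from the regression structure
#'
#' Standardizes the generated covariates with the generator's own spec,
#' draws the latent date, overdispersion and population effects from their
#' normal laws, evaluates the exact model linear predictor, and draws
#' `y ~ Binomial(n, inverse-logit(eta))` per female. The realized latent
#' effects and per-female probabilities are returned for recovery testing.
#'
#' @param females,populations Covariate tables from [draw_covariates()].
#' @param true_parameters List with `fixed` and `sigma2` as in
#'   [default_true_parameters()].
#' @param seed Integer seed.
#' @return A list: `females` (with `y` filled in), `populations`, `truth`
#'   (true parameters as a `fert_params` with the realized latents, plus
#'   `eta` and `p` per female, and the design's standardization spec).
#' @export
simulate_outcomes_regression <- function(females, populations,
                                         true_parameters = default_true_parameters(),
                                         seed = 1) {
  set.seed(seed)
  design <- build_design(females, populations)
  s2 <- true_parameters$sigma2
  params <- model_parameters(
    design,
    fixed = true_parameters$fixed,
    sigma2 = s2,
    gamma = rnorm(length(design$date_levels), 0, sqrt(s2[["sigma2_gamma"]])),
    eps = rnorm(length(design$y), 0, sqrt(s2[["sigma2_eps"]])),
    omega = rnorm(length(design$pop_levels), 0, sqrt(s2[["sigma2_omega"]]))
  )
  eta <- linear_predictor(design, params)
  p <- inv_logit(eta)
  y <- rbinom(length(p), design$n, p)

  out <- design$females
  out$y <- as.integer(y)
  out <- out[names(females)]
  list(
    females = out,
    populations = populations,
    truth = list(params = params, eta = eta, p = p, spec = design$spec)
  )
}

#' Simulate a complete synthetic study
#'
#' Draws covariates for the scenario's sampling design, then fertilization
#' outcomes from the scenario's flavor: `"regression"` uses the model's own
#' binomial-logit structure with known coefficients
#' ([simulate_outcomes_regression()]); `"mechanistic"` uses the
#' sperm-dilution scene ([simulate_outcomes_mechanistic()]) in which
#' positive density dependence is a local, flow-conditioned emergent
#' pattern.
#'
#' @param scenario A [study_scenario()].
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A list `females`, `populations`, `truth` (flavor-specific ground
#'   truth annotations).
#' @export
simulate_study <- function(scenario = study_scenario(), seed = 1) {
  cov <- draw_covariates(scenario, seed = seed)
  if (scenario$flavor == "regression") {
    simulate_outcomes_regression(cov$females, cov$populations,
                                 scenario$true_parameters,
                                 seed = seed + 1L)
  } else {
    scene <- build_mechanistic_scene(cov, scenario$mechanistic,
                                     seed = seed + 1L)
    simulate_outcomes_mechanistic(scene, seed = seed + 2L)
  }
}

#' Write a simulated study to disk
#'
#' Writes `females.csv`, `pops.csv` and `truth.json` (true parameters and
#' latent/exposure annotations) under a directory.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_females_csv(sim$females, file.path(dir, "females.csv"))
  write_populations_csv(sim$populations, file.path(dir, "pops.csv"))
  truth <- sim$truth
  if (!is.null(truth$params) && inherits(truth$params, "fert_params")) {
    truth$params <- as.list(as_param_vector(truth$params))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
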