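# End-to-end pipeline driver: validate -> (simulate) -> fit -> check ->
# report, with a manifest capturing configuration, seeds and output hashes.

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param scenario A [study_scenario()] to simulate from, or `NULL` to read
#'   existing tables.
#' @param females_csv,populations_csv Input paths (used when `scenario` is
#'   `NULL`).
#' @param mcmc An [mcmc_config()].
#' @param prior A [prior_spec()].
#' @param seed Integer seed for simulation and checking.
#' @return A list of class `fert_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, scenario = NULL, females_csv = NULL,
                            populations_csv = NULL, mcmc = mcmc_config(),
                            prior = prior_spec(), seed = 1) {
  if (is.null(scenario) && (is.null(females_csv) || is.null(populations_csv))) {
    abort("either a scenario or both input CSV paths must be given",
          class = "crypticallee_error_configuration")
  }
  structure(
    list(out_dir = out_dir, scenario = scenario, females_csv = females_csv,
         populations_csv = populations_csv, mcmc = mcmc, prior = prior,
         seed = as.integer(seed)),
    class = "fert_pipeline_config"
  )
}

stage_fail <- function(stage, parent) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage,
                conditionMessage(parent)),
        class = "crypticallee_error_pipeline", stage = stage)
}

#' Run the full analysis pipeline
#'
#' Executes validate -> (simulate) -> fit -> check -> report. Writes, under
#' `out_dir`: the study tables (`females.csv`, `pops.csv`, plus
#' `truth.json` when simulating), the standardization sidecar
#' (`standardization.json`), posterior draws (`draws.csv`, long format),
#' the posterior summary (`summary.csv`), the effect table
#' (`effects.csv`), prediction curves (`curves.csv`), the posterior
#' predictive check (`ppc.json`) and a `manifest.json` with stages, seeds
#' and md5 hashes of every output. Any stage failure aborts with a
#' stage-named error; outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted model (`fit`), `summary`,
#'   `effects`, `ppc`, `curves` and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fert_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  path <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$scenario)) {
    sim <- tryCatch(simulate_study(config$scenario, seed = config$seed),
                    error = function(e) stage_fail("simulate", e))
    write_simulation(sim, config$out_dir)
    females <- sim$females
    populations <- sim$populations
    stages <- c(stages, "simulate")
  } else {
    females <- tryCatch(read_females_csv(config$females_csv),
                        error = function(e) stage_fail("validate", e))
    populations <- tryCatch(read_populations_csv(config$populations_csv),
                            error = function(e) stage_fail("validate", e))
    write_females_csv(females, path("females.csv"))
    write_populations_csv(populations, path("pops.csv"))
  }

  validation <- tryCatch(
    validate_study_data(females, populations, quiet = TRUE),
    error = function(e) stage_fail("validate", e)
  )
  stages <- c(stages, "validate")

  fit <- tryCatch(
    fit_fertilization_model(females, populations, prior = config$prior,
                            config = config$mcmc),
    error = function(e) stage_fail("fit", e)
  )
  write_standardization_json(fit$design, path("standardization.json"))
  write_draws_csv(fit, path("draws.csv"))
  summary <- summarize_draws(fit)
  readr::write_csv(summary, path("summary.csv"))
  stages <- c(stages, "fit")

  ppc <- tryCatch(
    bayesian_p_value(fit, seed = config$seed + 1L),
    error = function(e) stage_fail("check", e)
  )
  jsonlite::write_json(
    list(discrepancy = ppc$discrepancy, p_value = ppc$p_value,
         n_clipped = ppc$n_clipped),
    path("ppc.json"), auto_unbox = TRUE, digits = NA
  )
  stages <- c(stages, "check")

  effects <- tryCatch(effect_table(summary),
                      error = function(e) stage_fail("report", e))
  readr::write_csv(effects, path("effects.csv"))
  curves <- predict_fertilization_curve(fit)
  readr::write_csv(curves, path("curves.csv"))
  stages <- c(stages, "report")

  outputs <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    stages = stages,
    seed = config$seed,
    mcmc = unclass(config$mcmc),
    package_version = as.character(utils::packageVersion("crypticallee")),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, outputs)))
  )
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(fit = fit, validation = validation, summary = summary,
                 effects = effects, ppc = ppc, curves = curves,
                 manifest = manifest))
}
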