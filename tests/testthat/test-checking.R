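# a minimal hand-built fit object: a design plus draw matrices whose columns
# follow the sampler layout, enough for the checking and reporting functions
manual_fit <- function(design, fixed_draws, eps = TRUE) {
  n_draw <- nrow(fixed_draws)
  lay <- crypticallee:::param_layout(design, names(design$X),
                                     include_gamma = TRUE, include_eps = eps,
                                     include_omega = TRUE)
  draws <- matrix(0, n_draw, lay$n_total,
                  dimnames = list(NULL, lay$names))
  draws[, colnames(fixed_draws)] <- fixed_draws
  draws[, "sigma2_gamma"] <- 1
  draws[, "sigma2_eps"] <- 1
  draws[, "sigma2_omega"] <- 1
  structure(
    list(draws = list(draws), design = design, prior = prior_spec(),
         config = mcmc_config(seed = 1), columns = names(design$X),
         include = list(gamma = TRUE, eps = eps, omega = TRUE),
         layout = lay),
    class = "fert_fit"
  )
}

zero_draws <- function(n_draw = 1) {
  matrix(0, n_draw, 13,
         dimnames = list(NULL, crypticallee:::FIXED_EFFECT_NAMES))
}

test_that("Bayesian p-value flags gross misfit and accepts self-consistent data", {
  sim <- simulate_study(study_scenario(), seed = 51)
  d <- build_design(sim$females, sim$populations)

  # all-zero parameters fit data that were NOT generated at p = 0.5: with
  # observed y forced to zero the replicated discrepancies can never reach
  # the observed one
  d0 <- d
  d0$y <- rep(0L, length(d$y))
  fit0 <- manual_fit(d0, zero_draws(200))
  ppc0 <- bayesian_p_value(fit0, seed = 3)
  expect_lt(ppc0$p_value, 0.01)

  # data generated and fitted under the same law: the posterior predictive
  # p-value stays strictly away from both tails across seeds
  pvals <- sapply(1:10, function(s) {
    ss <- simulate_study(study_scenario(), seed = 1000 + s)
    ft <- quick_fit(ss, seed = 2000 + s, n_iterations = 4000,
                    n_burnin = 1500)
    bayesian_p_value(ft, seed = 3000 + s)$p_value
  })
  expect_true(all(pvals > 0.01 & pvals < 0.99))
})

test_that("discrepancy measures are pluggable and invariants hold", {
  sim <- simulate_study(study_scenario(), seed = 52)
  fit <- quick_fit(sim, seed = 8, n_iterations = 3000, n_burnin = 1000)
  for (disc in c("pearson_chi2", "abs_residual", "deviance")) {
    ppc <- bayesian_p_value(fit, discrepancy = disc, seed = 2)
    expect_gte(ppc$p_value, 0)
    expect_lte(ppc$p_value, 1)
    expect_equal(ppc$p_value, mean(ppc$draws$t_rep >= ppc$draws$t_obs))
    expect_equal(nrow(ppc$draws), nrow(fit$draws[[1]]) * 2)
  }
  expect_error(bayesian_p_value(fit, discrepancy = "nope"),
               class = "crypticallee_error_configuration")
  td <- tidy(bayesian_p_value(fit, seed = 2))
  expect_true(all(c("discrepancy", "p_value") %in% names(td)))
})

test_that("the effect table flags exactly the intervals excluding zero", {
  s <- tibble::tibble(
    parameter = crypticallee:::FIXED_EFFECT_NAMES,
    median = 0, lower = -0.2, upper = 0.4,
    p_positive = 0.6, p_negative = 0.4, rhat = 1, n_draws = 100,
    significant = FALSE
  )
  s$median[s$parameter == "beta_den_x_vel"] <- -0.5
  s$lower[s$parameter == "beta_den_x_vel"] <- -0.9
  s$upper[s$parameter == "beta_den_x_vel"] <- -0.1
  s$p_negative[s$parameter == "beta_den_x_vel"] <- 0.99
  s$p_positive[s$parameter == "beta_den_x_vel"] <- 0.01
  s$significant <- s$lower > 0 | s$upper < 0

  et <- effect_table(s)
  expect_equal(nrow(et), 13)
  expect_equal(et$significant, et$parameter == "beta_den_x_vel")
  expect_equal(et$sign[et$parameter == "beta_den_x_vel"], "negative")
  expect_equal(et$p_sign[et$parameter == "beta_den_x_vel"], 0.99)
  expect_equal(unique(et$level[grepl("^alpha", et$parameter)]), "population")
  # pure function of the summary: bit-identical on re-run
  expect_identical(et, effect_table(s))
})

test_that("prediction curves condition on flow percentiles and stay coherent", {
  sim <- simulate_study(study_scenario(), seed = 53)
  d <- build_design(sim$females, sim$populations)

  flat <- manual_fit(d, zero_draws(1))
  cv <- predict_fertilization_curve(flat, den_grid = seq(0, 60, 10))
  expect_true(all(abs(cv$p_median - 0.5) < 1e-12))
  expect_true(all(cv$p_lower == cv$p_median & cv$p_upper == cv$p_median))
  expect_equal(sort(unique(cv$cond_prob)), c(0.25, 0.75))

  # known single draw with a positive density effect damped by velocity
  dr <- zero_draws(1)
  dr[, "beta_den"] <- 1
  dr[, "beta_den_x_vel"] <- -1
  known <- manual_fit(d, dr)
  cv2 <- predict_fertilization_curve(known, den_grid = seq(0, 60, 5))
  lo <- cv2[cv2$cond_var == "vel" & cv2$cond_prob == 0.25, ]
  hi <- cv2[cv2$cond_var == "vel" & cv2$cond_prob == 0.75, ]
  expect_true(all(diff(lo$p_median) > 0))
  # the fast-water curve is flatter: smaller total rise and a smaller
  # median pointwise slope
  expect_lt(max(hi$p_median) - min(hi$p_median),
            max(lo$p_median) - min(lo$p_median))
  expect_lt(median(abs(diff(hi$p_median))), median(abs(diff(lo$p_median))))

  # den axis is reported in natural units over the observed range
  expect_gte(min(cv2$den), 0)
  expect_equal(nrow(lo), length(seq(0, 60, 5)))

  empty <- manual_fit(d, zero_draws(1))
  empty$draws <- list(empty$draws[[1]][0, , drop = FALSE])
  expect_error(predict_fertilization_curve(empty),
               class = "crypticallee_error_validation")
})

test_that("plots are built from fitted objects", {
  sim <- simulate_study(study_scenario(), seed = 54)
  fit <- quick_fit(sim, seed = 9, n_iterations = 3000, n_burnin = 1000)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_interaction_panels(fit), "ggplot")
  expect_s3_class(autoplot(bayesian_p_value(fit, seed = 1)), "ggplot")
})

test_that("the pipeline runs end to end and writes a hashed manifest", {
  withr::with_tempdir({
    cfg <- pipeline_config(
      out_dir = "run1",
      scenario = study_scenario(
        n_females_year1 = c(5, 6, 7, 7, 8, 7),
        n_females_year2 = integer(0), resampled = integer(0)
      ),
      mcmc = mcmc_config(n_iterations = 2000, n_burnin = 500, thin = 5,
                         n_chains = 2, seed = 99),
      seed = 5
    )
    res <- run_pipeline(cfg)
    expect_equal(res$manifest$stages,
                 c("simulate", "validate", "fit", "check", "report"))
    for (f in c("females.csv", "pops.csv", "truth.json", "draws.csv",
                "summary.csv", "effects.csv", "curves.csv", "ppc.json",
                "standardization.json", "manifest.json")) {
      expect_true(file.exists(file.path("run1", f)))
    }
    expect_true(all(nchar(unlist(res$manifest$outputs)) == 32))

    bad <- pipeline_config(out_dir = "run2", females_csv = "absent.csv",
                           populations_csv = "absent2.csv")
    err <- tryCatch(run_pipeline(bad), error = function(e) e)
    expect_s3_class(err, "crypticallee_error_pipeline")
    expect_equal(err$stage, "validate")
  })
})
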