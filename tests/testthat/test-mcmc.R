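test_that("chains have the configured shape and are reproducible", {
  sim <- simulate_study(study_scenario(), seed = 31)
  cfg <- mcmc_config(n_iterations = 2000, n_burnin = 500, thin = 5,
                     n_chains = 2, seed = 41)
  fit <- fit_fertilization_model(sim$females, sim$populations, config = cfg)
  expect_length(fit$draws, 2)
  expect_equal(nrow(fit$draws[[1]]), (2000 - 500) / 5)
  expect_true(all(crypticallee:::FIXED_EFFECT_NAMES %in%
                    colnames(fit$draws[[1]])))
  expect_true(all(c("sigma2_gamma", "sigma2_eps", "sigma2_omega") %in%
                    colnames(fit$draws[[1]])))
  # latent blocks sized by the design's index sets
  expect_equal(fit$layout$n_total,
               13 + 3 + length(fit$design$date_levels) +
                 length(fit$design$y) + length(fit$design$pop_levels))

  fit2 <- fit_fertilization_model(sim$females, sim$populations, config = cfg)
  expect_identical(fit$draws, fit2$draws)

  cfg3 <- mcmc_config(n_iterations = 2000, n_burnin = 500, thin = 5,
                      n_chains = 2, seed = 42)
  fit3 <- fit_fertilization_model(sim$females, sim$populations, config = cfg3)
  expect_false(identical(fit$draws[[1]], fit3$draws[[1]]))

  # variance draws stay inside the uniform prior support
  pooled <- posterior_draws(fit)
  for (s in c("sigma2_gamma", "sigma2_eps", "sigma2_omega")) {
    expect_true(all(pooled[, s] > 0 & pooled[, s] < 100))
  }
})

test_that("step sizes freeze after burn-in: post-burn-in draws replay exactly", {
  sim <- simulate_study(study_scenario(), seed = 31)
  cfg_long <- mcmc_config(n_iterations = 3000, n_burnin = 1000, thin = 2,
                          n_chains = 1, seed = 13)
  cfg_short <- mcmc_config(n_iterations = 2000, n_burnin = 1000, thin = 2,
                           n_chains = 1, seed = 13)
  long <- fit_fertilization_model(sim$females, sim$populations,
                                  config = cfg_long)
  short <- fit_fertilization_model(sim$females, sim$populations,
                                   config = cfg_short)
  n_short <- nrow(short$draws[[1]])
  expect_identical(long$draws[[1]][seq_len(n_short), ], short$draws[[1]])
})

test_that("with no data the sampler reproduces the prior", {
  d <- build_design(
    tibble::tibble(
      female_id = c("a", "b"), population_id = c("A", "B"),
      date = c("d", "e"), year = 2012L, y = c(10L, 20L), n = 300L,
      den = c(1, 2), vel = c(1, 2), dep = c(1, 2), sub = c(1, 2),
      loc = c(0, 1), shell = c(50, 60), usable = TRUE
    ),
    tibble::tibble(population_id = c("A", "B"), year = 2012L,
                   p_den = c(1, 3), cat = c(2, 5))
  )
  d$X <- d$X[0, "intercept", drop = FALSE]
  d$y <- integer(0)
  d$n <- integer(0)
  d$date_id <- integer(0)
  d$pop_id <- integer(0)
  fit <- run_chains(d, prior = prior_spec(coef_variance = 4),
                    columns = "intercept",
                    config = mcmc_config(6000, 1000, 2, 2, seed = 3),
                    include_gamma = FALSE, include_eps = FALSE,
                    include_omega = FALSE)
  dr <- posterior_draws(fit, "alpha_global")
  expect_lt(abs(mean(dr)), 0.35)
  expect_gt(sd(dr), 1.7)
  expect_lt(sd(dr), 2.3)
})

test_that("the single-proportion reduction matches the conjugate posterior", {
  # one female, y = 150 / 300, intercept-only, no latent effects: the
  # posterior of p = inverse-logit(alpha) is, up to the near-flat prior,
  # the Beta(y + 1, n - y + 1) conjugate posterior
  d <- single_proportion_design()
  fit <- run_chains(d, columns = "intercept",
                    config = mcmc_config(20000, 4000, 4, 2, seed = 71),
                    include_gamma = FALSE, include_eps = FALSE,
                    include_omega = FALSE)
  p_draws <- inv_logit(posterior_draws(fit, "alpha_global"))
  q_mcmc <- quantile(p_draws, c(0.025, 0.5, 0.975))
  q_true <- qbeta(c(0.025, 0.5, 0.975), 150 + 1, 150 + 1)
  expect_true(all(abs(q_mcmc - q_true) < 0.015))
})

test_that("split R-hat separates converged from divergent chains", {
  set.seed(61)
  same <- matrix(rnorm(2000), ncol = 2)
  expect_lt(rhat(same), 1.05)
  expect_gt(rhat(same), 0.99)

  apart <- cbind(rnorm(1000, 0), rnorm(1000, 100))
  expect_gt(rhat(apart), 1.5)

  # within-chain drift is caught by the split variant
  drift <- cbind(seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1),
                 seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1))
  expect_gt(rhat(drift), 1.5)

  expect_equal(rhat(matrix(2, 100, 3)), 1.0)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)),
               class = "crypticallee_error_diagnostic")
  expect_error(rhat(matrix(rnorm(8), ncol = 2)),
               class = "crypticallee_error_diagnostic")
  # list-of-chains input
  expect_lt(rhat(list(rnorm(500), rnorm(500))), 1.05)
})

test_that("posterior summaries report medians, intervals and sign probabilities", {
  sym <- matrix(rep(c(-1, 1), 500), ncol = 1,
                dimnames = list(NULL, "theta"))
  s <- summarize_draws(list(sym, sym), params = "theta")
  expect_equal(s$p_positive, 0.5)
  expect_equal(s$median, 0)

  pos <- matrix(rexp(1000) + 0.01, ncol = 1, dimnames = list(NULL, "theta"))
  s2 <- summarize_draws(list(pos, pos), params = "theta")
  expect_equal(s2$p_positive, 1)
  expect_true(s2$significant)
  expect_true(s2$lower <= s2$median && s2$median <= s2$upper)

  set.seed(5)
  norm1 <- matrix(rnorm(12000, 1, 1), ncol = 1,
                  dimnames = list(NULL, "theta"))
  s3 <- summarize_draws(list(norm1[1:6000, , drop = FALSE],
                             norm1[6001:12000, , drop = FALSE]),
                        params = "theta")
  expect_lt(abs(s3$p_positive - pnorm(1)), 0.01)
  expect_equal(s3$p_positive + s3$p_negative, 1)
})

test_that("tidy, glance and long-format export expose the fit", {
  sim <- simulate_study(study_scenario(), seed = 31)
  fit <- quick_fit(sim, seed = 7, n_iterations = 3000, n_burnin = 1000)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  expect_true(all(c("parameter", "median", "lower", "upper", "p_positive",
                    "rhat", "significant") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_females, 91L)
  expect_equal(gl$n_chains, 2L)

  long <- draws_long(fit, params = c("beta_den", "sigma2_eps"))
  expect_setequal(names(long), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(long), 2 * nrow(fit$draws[[1]]) * 2)
})
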