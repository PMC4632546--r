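test_that("identical seeds reproduce bit-identical datasets", {
  a <- simulate_study(study_scenario(), seed = 3)
  b <- simulate_study(study_scenario(), seed = 3)
  expect_identical(a, b)
  c <- simulate_study(study_scenario(), seed = 4)
  expect_false(identical(a$females$y, c$females$y))

  m1 <- make_cryptic_dataset(seed = 3)
  m2 <- make_cryptic_dataset(seed = 3)
  expect_identical(m1, m2)
})

test_that("drawn covariates respect the observed ranges and moments", {
  cov <- draw_covariates(study_scenario(), seed = 12)
  f <- cov$females
  expect_equal(nrow(f), 91L)
  expect_true(all(f$den >= 0 & f$den <= 79 & f$den == round(f$den)))
  expect_true(all(f$vel >= 0.2 & f$vel <= 76.5))
  expect_true(all(f$dep >= 10 & f$dep <= 62))
  expect_true(all(f$sub >= 1.3 & f$sub <= 3.3))
  expect_true(all(f$shell >= 53 & f$shell <= 114))
  expect_true(all(f$loc >= 0))
  expect_true(all(cov$populations$cat >= 19.1 & cov$populations$cat <= 252.6))
  expect_equal(nrow(cov$populations), 14L)

  # sample moments land near the observed table (within 15%, averaged over a
  # few seeds to keep the check sharp at n = 91)
  mom <- rowMeans(sapply(1:6, function(s) {
    cc <- draw_covariates(study_scenario(), seed = s)
    c(mean(cc$females$den), mean(cc$females$vel), sd(cc$females$vel),
      mean(cc$females$dep), sd(cc$females$dep), mean(cc$females$sub),
      mean(cc$females$shell))
  }))
  targets <- c(18.9, 16.5, 14.4, 29.7, 13.6, 2.7, 78.0)
  expect_true(all(abs(mom - targets) / targets < 0.15))

  # p_den is derived from the generated local densities
  rederived <- derive_population_density(f)
  joined <- dplyr::inner_join(rederived, cov$populations,
                              by = c("population_id", "year"))
  expect_equal(joined$p_den.x, joined$p_den.y)

  # infeasible truncation is rejected up front
  bad <- study_scenario()
  bad$covariates$dep$mean <- 5
  expect_error(draw_covariates(bad, seed = 1),
               class = "crypticallee_error_configuration")
})

test_that("regression outcomes follow the model's own law", {
  cov <- draw_covariates(study_scenario(), seed = 2)
  null_params <- list(
    fixed = setNames(numeric(13), crypticallee:::FIXED_EFFECT_NAMES),
    sigma2 = c(sigma2_gamma = 0, sigma2_eps = 0, sigma2_omega = 0)
  )
  sim <- simulate_outcomes_regression(cov$females, cov$populations,
                                      null_params, seed = 5)
  expect_true(all(sim$truth$p == 0.5))
  expect_lt(abs(mean(sim$females$y) / 300 - 0.5),
            3 * sqrt(0.25 / (300 * 91)))

  sat <- null_params
  sat$fixed[["alpha_global"]] <- 15
  sim2 <- simulate_outcomes_regression(cov$females, cov$populations, sat,
                                       seed = 5)
  expect_true(all(sim2$females$y == 300L))
})

test_that("an interaction in the truth shows up as velocity-dependent slopes", {
  sc <- study_scenario(n_females_year1 = rep(50, 100),
                       n_females_year2 = integer(0), resampled = integer(0))
  cov <- draw_covariates(sc, seed = 8)
  tp <- list(
    fixed = setNames(numeric(13), crypticallee:::FIXED_EFFECT_NAMES),
    sigma2 = c(sigma2_gamma = 0, sigma2_eps = 0, sigma2_omega = 0)
  )
  tp$fixed[["beta_den"]] <- 1
  tp$fixed[["beta_den_x_vel"]] <- -1
  sim <- simulate_outcomes_regression(cov$females, cov$populations, tp,
                                      seed = 9)
  f <- sim$females
  elogit <- log((f$y + 0.5) / (f$n - f$y + 0.5))
  zden <- scale(f$den)[, 1]
  terc <- cut(f$vel, quantile(f$vel, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = FALSE)
  slope_lo <- coef(lm(elogit[terc == 1] ~ zden[terc == 1]))[2]
  slope_hi <- coef(lm(elogit[terc == 3] ~ zden[terc == 3]))[2]
  expect_gt(slope_lo, 0.5)
  expect_lt(abs(slope_hi), abs(slope_lo) / 2)
})

test_that("maximum-likelihood refits recover the generator's coefficients", {
  # oracle: direct binomial ML on the generated design (no latent effects)
  sc <- study_scenario(n_females_year1 = rep(40, 50),
                       n_females_year2 = integer(0), resampled = integer(0))
  cov <- draw_covariates(sc, seed = 21)
  tp <- default_true_parameters()
  tp$sigma2[] <- 0
  sim <- simulate_outcomes_regression(cov$females, cov$populations, tp,
                                      seed = 22)
  d <- build_design(sim$females, sim$populations)
  X <- as.matrix(d$X[, -1])
  fit <- glm(cbind(d$y, d$n - d$y) ~ X, family = binomial())
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  names(est) <- names(se) <- c("alpha_global",
                               crypticallee:::FIXED_EFFECT_NAMES[-1])
  for (nm in names(est)) {
    expect_lt(abs(est[[nm]] - tp$fixed[[nm]]) / se[[nm]], 3.5)
  }
})

test_that("sperm exposure is additive, label-free and kernel-limited", {
  recv <- tibble::tibble(pos = c(0, 10), lateral = c(0, 0), lambda = c(2, 2))
  males <- tibble::tibble(pos = c(0, 5, 8), lateral = c(0, 0, 0),
                          count = c(3, 2, 1))
  e <- sperm_exposure(recv, males)
  expect_equal(e[1], 3 + 2 * exp(-5 / 2) + exp(-8 / 2), tolerance = 1e-12)

  # no males, relabeling, additivity over disjoint sets
  expect_equal(sperm_exposure(recv, males[0, ]), c(0, 0))
  expect_equal(sperm_exposure(recv, males[c(3, 1, 2), ]), e)
  expect_equal(sperm_exposure(recv, males[1:2, ]) +
                 sperm_exposure(recv, males[3, ]), e)

  # doubling counts doubles exposure; more males never decrease it
  males2 <- males
  males2$count <- males$count * 2
  expect_equal(sperm_exposure(recv, males2), 2 * e)

  # lambda -> Inf flattens the kernel (everyone sees every male equally);
  # lambda -> 0 keeps only co-located males
  flat <- recv
  flat$lambda <- 1e9
  expect_equal(sperm_exposure(flat, males), rep(sum(males$count), 2),
               tolerance = 1e-6)
  sharp <- recv
  sharp$lambda <- 1e-9
  expect_equal(sperm_exposure(sharp, males), c(3, 0))

  # cross-stream separation reduces exposure
  offset <- recv
  offset$lateral <- c(4, 4)
  expect_true(all(sperm_exposure(offset, males) < e))
})

test_that("dilution length increases with velocity and depth", {
  expect_gt(dilution_lambda(30, 30), dilution_lambda(5, 30))
  expect_gt(dilution_lambda(10, 50), dilution_lambda(10, 15))
  v <- seq(1, 70, length.out = 20)
  expect_true(all(diff(dilution_lambda(v, 30)) > 0))
})

test_that("the cryptic dataset hides the density effect at the population scale", {
  # brute-force generator check on an oversampled design: population mean
  # density says nothing about population mean fertilization, while local
  # density predicts it strongly in the slowest water
  sc <- study_scenario(n_females_year1 = rep(25, 200),
                       n_females_year2 = integer(0), resampled = integer(0),
                       flavor = "mechanistic")
  sim <- make_cryptic_dataset(sc, seed = 11)
  f <- sim$females
  f$rate <- f$y / f$n
  popm <- f |>
    dplyr::group_by(.data$population_id, .data$year) |>
    dplyr::summarise(mr = mean(.data$rate), .groups = "drop") |>
    dplyr::inner_join(sim$populations, by = c("population_id", "year"))
  expect_lt(abs(cor(popm$p_den, popm$mr)), 0.2)

  slow <- f[f$vel <= quantile(f$vel, 0.25), ]
  expect_gt(cor(slow$den, slow$rate), 0.4)

  # truth annotations cover every female
  expect_length(sim$truth$p, nrow(f))
  expect_true(all(sim$truth$exposure >= 0))

  expect_error(make_cryptic_dataset(study_scenario(), seed = 1),
               class = "crypticallee_error_configuration")
})
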