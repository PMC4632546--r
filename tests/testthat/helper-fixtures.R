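# In-code fixtures shared across test files.

# small hand-built study: 2 populations x 2-3 females with exactly known values
tiny_females <- function() {
  tibble::tibble(
    female_id = c("a1", "a2", "a3", "b1", "b2"),
    population_id = c("A", "A", "A", "B", "B"),
    date = c("d1", "d1", "d1", "d2", "d2"),
    year = 2012L,
    y = c(150L, 30L, 280L, 0L, 300L),
    n = 300L,
    den = c(10, 20, 30, 5, 15),
    vel = c(5, 10, 20, 8, 40),
    dep = c(15, 25, 35, 20, 50),
    sub = c(2.0, 2.5, 3.0, 1.5, 2.8),
    loc = c(0, 3, 6, 0, 4),
    shell = c(60, 75, 90, 70, 100),
    usable = TRUE
  )
}

tiny_populations <- function() {
  tibble::tibble(
    population_id = c("A", "B"),
    year = 2012L,
    p_den = c(20, 10),
    cat = c(50, 120)
  )
}

tiny_design <- function() {
  build_design(tiny_females(), tiny_populations())
}

# random parameter set sized for a design, with variances inside the prior
# support
random_params <- function(design, sd = 0.5) {
  model_parameters(
    design,
    fixed = setNames(rnorm(13, 0, sd), crypticallee:::FIXED_EFFECT_NAMES),
    sigma2 = c(sigma2_gamma = runif(1, 0.1, 5), sigma2_eps = runif(1, 0.1, 5),
               sigma2_omega = runif(1, 0.1, 5)),
    gamma = rnorm(length(design$date_levels), 0, sd),
    eps = rnorm(length(design$y), 0, sd),
    omega = rnorm(length(design$pop_levels), 0, sd)
  )
}

# a one-record intercept-only design for conjugate single-proportion checks
single_proportion_design <- function(y = 150L, n = 300L) {
  structure(
    list(
      X = tibble::tibble(intercept = 1),
      y = y, n = n,
      date_id = 1L, pop_id = 1L,
      date_levels = "d1|2012", pop_levels = "A|2012",
      spec = tibble::tibble(covariate = character(0), mean = numeric(0),
                            sd = numeric(0), level = character(0)),
      females = tibble::tibble(female_id = "f1", y = y, n = n)
    ),
    class = "fert_design"
  )
}

# the field roster: 49 + 50 collected over two seasons, 8 with
# indiscernible egg samples
study_roster <- function() {
  n_tot <- 99L
  indiscernible <- c(3L, 17L, 25L, 40L, 52L, 66L, 80L, 97L)
  tibble::tibble(
    female_id = sprintf("f%02d", seq_len(n_tot)),
    population_id = rep(sprintf("P%02d", 1:11), length.out = n_tot),
    date = rep(c("2012-07-01", "2013-06-27"), times = c(49L, 50L)),
    year = rep(c(2012L, 2013L), times = c(49L, 50L)),
    y = 150L, n = 300L,
    den = 10, vel = 10, dep = 30, sub = 2.5, loc = 1, shell = 80,
    usable = !(seq_len(n_tot) %in% indiscernible)
  )
}

# a quick reduced-chain fit used by several checking tests
quick_fit <- function(sim, seed = 7, n_iterations = 6000, n_burnin = 2000,
                      thin = 4, n_chains = 2) {
  fit_fertilization_model(
    sim$females, sim$populations,
    config = mcmc_config(n_iterations = n_iterations, n_burnin = n_burnin,
                         thin = thin, n_chains = n_chains, seed = seed)
  )
}
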