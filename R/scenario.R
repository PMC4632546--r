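# Study-design scenario: sampling layout and covariate distributions matched
# to the field survey (14 population replicates over two years, 91 usable
# females, covariate moments and ranges as observed), plus the true model
# parameters used by the outcome simulators.

#' Truncated-normal parameters matched to target moments
#'
#' Solves for the underlying (mu, sigma) of a normal truncated to
#' \[lo, hi\] whose *truncated* mean and sd equal the targets, so generated
#' samples reproduce the reported summary statistics rather than the
#' pre-truncation ones.
#'
#' @param mean,sd Target mean and sd of the truncated distribution (for
#'   `icc > 0`: of the marginal over sites).
#' @param lo,hi Truncation bounds.
#' @param icc Share of the underlying variance attributed to a site
#'   (population) level shift; the solver matches the *marginal* moments of
#'   the resulting two-level truncated draw.
#' @return A list `mu`, `sigma`, `lo`, `hi`, `icc`.
#' @keywords internal
truncnorm_match <- function(mean, sd, lo, hi, icc = 0) {
  if (mean < lo || mean > hi) {
    abort(sprintf("target mean %.3g outside truncation bounds [%.3g, %.3g]",
                  mean, lo, hi),
          class = "crypticallee_error_configuration")
  }
  # site-effect quadrature grid (exact at icc = 0: single node)
  if (icc > 0) {
    z <- seq(-4, 4, length.out = 41)
    w <- dnorm(z)
    w <- w / sum(w)
  } else {
    z <- 0
    w <- 1
  }
  cond_moments <- function(mu, s) {
    a <- (lo - mu) / s
    b <- (hi - mu) / s
    zz <- pnorm(b) - pnorm(a)
    da <- dnorm(a); db <- dnorm(b)
    tm <- mu + s * (da - db) / pmax(zz, 1e-12)
    tv <- s^2 * (1 + (a * da - b * db) / pmax(zz, 1e-12) -
                   ((da - db) / pmax(zz, 1e-12))^2)
    list(m = tm, v = pmax(tv, 0))
  }
  marginal <- function(mu, s) {
    mus <- mu + s * sqrt(icc) * z
    cm <- cond_moments(mus, s * sqrt(1 - icc))
    m1 <- sum(w * cm$m)
    m2 <- sum(w * (cm$v + cm$m^2))
    c(m1, sqrt(max(m2 - m1^2, 0)))
  }
  obj <- function(par) {
    m <- marginal(par[1], exp(par[2]))
    if (anyNA(m)) return(1e10)
    (m[1] - mean)^2 / max(sd, 1)^2 + (m[2] - sd)^2 / max(sd, 1)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi, icc = icc)
}

rtruncnorm_matched <- function(n, tn) {
  u <- runif(n, pnorm(tn$lo, tn$mu, tn$sigma), pnorm(tn$hi, tn$mu, tn$sigma))
  qnorm(u, tn$mu, tn$sigma)
}

# hierarchical variant: a site (population) shift takes the fraction `icc`
# of the underlying variance, the remainder varies among females within site
rtruncnorm_site <- function(n, tn, z_site, icc) {
  mu_r <- tn$mu + tn$sigma * sqrt(icc) * z_site
  s_w <- tn$sigma * sqrt(1 - icc)
  u <- runif(n, pnorm(tn$lo, mu_r, s_w), pnorm(tn$hi, mu_r, s_w))
  qnorm(u, mu_r, s_w)
}

# lognormal with given arithmetic mean/sd, truncated to [lo, hi] by inverse CDF
rtrunclnorm <- function(n, mean, sd, lo, hi) {
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  u <- runif(n, plnorm(lo, mu, sqrt(s2)), plnorm(hi, mu, sqrt(s2)))
  qlnorm(u, mu, sqrt(s2))
}

# overdispersed integer counts, truncated to [0, hi] by resampling
rtruncnbinom <- function(n, mu, size, hi) {
  x <- rnbinom(n, mu = mu, size = size)
  for (tries in 1:50) {
    over <- x > hi
    if (!any(over)) break
    x[over] <- rnbinom(sum(over), mu = mu, size = size)
  }
  pmin(x, hi)
}

#' Default true model parameters for the regression scenario
#'
#' Ground truth used by [simulate_outcomes_regression()]: a strong positive
#' local-density effect that is damped by current velocity and (more weakly)
#' by depth, null population-level effects, and moderate variance
#' components. Coefficients are on the standardized-covariate logit scale.
#'
#' @return A list with `fixed` (named, 13 entries) and `sigma2` (named, 3).
#' @export
default_true_parameters <- function() {
  list(
    fixed = c(
      alpha_global = 1.0,
      alpha_pden = 0, alpha_cat = 0, alpha_pden_x_cat = 0,
      beta_den = 0.8, beta_vel = 0.3, beta_dep = -0.2, beta_sub = 0.1,
      beta_den_x_vel = -0.6, beta_den_x_dep = -0.35, beta_den_x_sub = 0,
      beta_loc = 0.2, beta_shell = 0
    ),
    sigma2 = c(sigma2_gamma = 0.25, sigma2_eps = 0.5, sigma2_omega = 0.25)
  )
}

#' Study-design scenario
#'
#' Configuration of the synthetic study: sampling layout (population
#' replicates per year and females per replicate, defaulting to the field
#' design: 10 populations in the first year with 1-12 females each, 4 of
#' them re-sampled the next year with 4-20 females each, 91 females total),
#' covariate distribution parameters (mean, sd, range as observed), the true
#' model parameters, and the scenario flavor.
#'
#' @param n_females_year1,n_females_year2 Integer vectors of females per
#'   population replicate in each year.
#' @param resampled Indices of year-1 populations re-sampled in year 2.
#' @param covariates Named list of distribution settings; see
#'   [default_covariate_distributions()].
#' @param true_parameters As [default_true_parameters()].
#' @param flavor `"regression"` (outcomes from the model's own structure) or
#'   `"mechanistic"` (sperm-dilution scene).
#' @param mechanistic Constants for the mechanistic scene; see
#'   [default_mechanistic_constants()].
#' @return A list of class `fert_scenario`.
#' @export
study_scenario <- function(n_females_year1 = c(1, 2, 3, 3, 4, 5, 6, 7, 8, 10),
                           n_females_year2 = c(4, 8, 12, 18),
                           resampled = seq_along(n_females_year2),
                           covariates = default_covariate_distributions(),
                           true_parameters = default_true_parameters(),
                           flavor = c("regression", "mechanistic"),
                           mechanistic = default_mechanistic_constants()) {
  flavor <- match.arg(flavor)
  stopifnot(all(n_females_year1 >= 1), all(n_females_year2 >= 1),
            length(resampled) == length(n_females_year2),
            all(resampled %in% seq_along(n_females_year1)))
  structure(
    list(n_females_year1 = as.integer(n_females_year1),
         n_females_year2 = as.integer(n_females_year2),
         resampled = as.integer(resampled),
         covariates = covariates,
         true_parameters = true_parameters,
         flavor = flavor,
         mechanistic = mechanistic),
    class = "fert_scenario"
  )
}

#' Default covariate distributions
#'
#' Distribution settings reproducing the observed covariate table: local
#' density as overdispersed counts (mean 18.9, sd 18.6, range 0-79) around a
#' population mean density itself drawn to match the population-level row
#' (18.4, sd 11.0, range 0.5-31.8); truncated normals matched to the
#' observed moments for current velocity (16.5, 14.4, 0.2-76.5 cm/s), depth
#' (29.7, 13.6, 10-62 cm), substrate coarseness (2.7, 0.3, 1.3-3.3) and
#' shell length (mean 78 mm, range 53-114; sd not reported, set to 12); and
#' a truncated lognormal for catchment area (77.6, 63.5, 19.1-252.6 km^2).
#'
#' @return A named list of per-covariate parameter lists.
#' @export
default_covariate_distributions <- function() {
  list(
    # latent mean-density spread: the observed population-level sd (11.0)
    # includes quadrat sampling noise around the bed mean, which the
    # generator reproduces when local densities are averaged per replicate
    pop_den = list(mean = 18.4, sd = 8.5, lo = 0.5, hi = 31.8),
    den = list(size = 1.61, hi = 79),
    vel = list(mean = 16.5, sd = 14.4, lo = 0.2, hi = 76.5, icc = 0.5),
    dep = list(mean = 29.7, sd = 13.6, lo = 10, hi = 62, icc = 0.5),
    sub = list(mean = 2.7, sd = 0.3, lo = 1.3, hi = 3.3),
    shell = list(mean = 78.0, sd = 12.0, lo = 53, hi = 114),
    cat = list(mean = 77.6, sd = 63.5, lo = 19.1, hi = 252.6),
    transect_spacing = c(3, 5),
    females_per_transect = 2,
    channel_width = 8
  )
}

# beta rescaled to [lo, hi] with exact moment match: the closed-form choice
# for a bounded quantity whose sd is large relative to its range
scaledbeta_match <- function(mean, sd, lo, hi) {
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
    abort("target moments infeasible for the given bounds",
          class = "crypticallee_error_configuration")
  }
  nu <- m * (1 - m) / v - 1
  list(a = m * nu, b = (1 - m) * nu, lo = lo, hi = hi)
}

rscaledbeta <- function(n, sb) {
  sb$lo + (sb$hi - sb$lo) * stats::rbeta(n, sb$a, sb$b)
}

#' Draw covariates for a synthetic study
#'
#' Generates the per-female and per-population covariate tables for a
#' scenario: a transect layout per population replicate (transects 3-5 m
#' apart, females on transects, `loc` measured from the upstream-most
#' transect), local density as truncated overdispersed counts around a
#' population mean density, flow and body-size covariates from
#' moment-matched truncated distributions, catchment area constant per
#' population across years, and `p_den` derived as the mean of the drawn
#' local densities ([derive_population_density()]).
#'
#' @param scenario A [study_scenario()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with `females` (covariates only; `y` is 0 and `n` 300
#'   until an outcome simulator fills them in), `populations`, and `layout`
#'   (per-female transect positions, used by the mechanistic scene).
#' @export
draw_covariates <- function(scenario, seed = 1) {
  set.seed(seed)
  cv <- scenario$covariates
  tn_vel <- truncnorm_match(cv$vel$mean, cv$vel$sd, cv$vel$lo, cv$vel$hi,
                            icc = cv$vel$icc %||% 0)
  tn_dep <- truncnorm_match(cv$dep$mean, cv$dep$sd, cv$dep$lo, cv$dep$hi,
                            icc = cv$dep$icc %||% 0)
  tn_sub <- truncnorm_match(cv$sub$mean, cv$sub$sd, cv$sub$lo, cv$sub$hi)
  tn_shell <- truncnorm_match(cv$shell$mean, cv$shell$sd, cv$shell$lo,
                              cv$shell$hi)

  n_pop1 <- length(scenario$n_females_year1)
  reps <- tibble::tibble(
    population_id = c(sprintf("P%02d", seq_len(n_pop1)),
                      sprintf("P%02d", scenario$resampled)),
    year = c(rep(2012L, n_pop1),
             rep(2013L, length(scenario$n_females_year2))),
    n_females = c(scenario$n_females_year1, scenario$n_females_year2),
    # one sampling date per population in year 1; year 2 surveyed over two
    # consecutive dates
    date = c(sprintf("2012-%02d", seq_len(n_pop1)),
             sprintf("2013-%02d", 1 + (seq_along(scenario$n_females_year2) %% 2)))
  )

  cat_by_pop <- setNames(
    rtrunclnorm(n_pop1, cv$cat$mean, cv$cat$sd, cv$cat$lo, cv$cat$hi),
    sprintf("P%02d", seq_len(n_pop1))
  )
  sb_pden <- scaledbeta_match(cv$pop_den$mean, cv$pop_den$sd,
                              cv$pop_den$lo, cv$pop_den$hi)
  mu_den <- rscaledbeta(nrow(reps), sb_pden)
  z_vel_site <- rnorm(nrow(reps))
  z_dep_site <- rnorm(nrow(reps))

  females <- purrr::pmap_dfr(
    list(reps$population_id, reps$year, reps$n_females, reps$date,
         seq_len(nrow(reps))),
    function(pid, yr, nf, date, r) {
      n_transects <- min(10L, max(1L, ceiling(nf / cv$females_per_transect)))
      spacing <- runif(max(n_transects - 1, 1), cv$transect_spacing[1],
                       cv$transect_spacing[2])
      pos_up <- c(0, cumsum(spacing))[seq_len(n_transects)] # from upstream edge
      transect_of <- sort(rep_len(seq_len(n_transects), nf))
      tibble::tibble(
        female_id = sprintf("%s-%d-%02d", pid, yr, seq_len(nf)),
        population_id = pid, date = date, year = yr,
        y = 0L, n = 300L,
        den = rtruncnbinom(nf, mu_den[r], cv$den$size, cv$den$hi),
        vel = rtruncnorm_site(nf, tn_vel, z_vel_site[r], cv$vel$icc %||% 0),
        dep = rtruncnorm_site(nf, tn_dep, z_dep_site[r], cv$dep$icc %||% 0),
        sub = rtruncnorm_matched(nf, tn_sub),
        loc = pos_up[transect_of] + runif(nf, 0, 0.5),
        shell = rtruncnorm_matched(nf, tn_shell),
        usable = TRUE,
        transect = transect_of,
        transect_pos = pos_up[transect_of],
        # cross-stream position on the transect (transects run perpendicular
        # to the flow); used by the mechanistic scene's distance kernel
        lateral = runif(nf, 0, cv$channel_width %||% 8)
      )
    }
  )

  populations <- derive_population_density(females) |>
    dplyr::mutate(cat = unname(cat_by_pop[.data$population_id])) |>
    dplyr::arrange(.data$year, .data$population_id)

  layout <- females[c("female_id", "population_id", "year", "loc",
                      "transect", "transect_pos", "lateral")]
  females$transect <- NULL
  females$transect_pos <- NULL
  females$lateral <- NULL
  list(females = females, populations = populations, layout = layout)
}
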