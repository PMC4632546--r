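# Exact numerical definition of the two-level binomial-logit model: linear
# predictor, binomial likelihood, vague priors, and the joint log-posterior
# over fixed effects, variance components and latent random effects.
#
# Model, on the logit scale, for female i in population j and year t:
#   logit p = alpha_{j,t}
#             + beta_den*DEN + beta_vel*VEL + beta_dep*DEP + beta_sub*SUB
#             + beta_den_x_vel*DEN*VEL + beta_den_x_dep*DEN*DEP
#             + beta_den_x_sub*DEN*SUB + beta_loc*LOC + beta_shell*SHELL
#             + gamma_{k(j),t} + eps_i
#   alpha_{j,t} = alpha_global + alpha_pden*P_DEN + alpha_cat*CAT
#                 + alpha_pden_x_cat*P_DEN*CAT + omega_{j,t}
#   y ~ Binomial(n = 300, p);  gamma ~ N(0, sigma2_gamma);
#   eps ~ N(0, sigma2_eps) (observation-level overdispersion);
#   omega ~ N(0, sigma2_omega).

SIGMA2_NAMES <- c("sigma2_gamma", "sigma2_eps", "sigma2_omega")

#' Model parameter container
#'
#' All fixed effects, variance components and latent random-effect vectors of
#' the hierarchical model, sized for a given design. Unspecified components
#' default to zero.
#'
#' @param design A `fert_design` from [build_design()].
#' @param fixed Named numeric vector over (a subset of) the 13 fixed effects:
#'   `alpha_global`, `alpha_pden`, `alpha_cat`, `alpha_pden_x_cat`,
#'   `beta_den`, `beta_vel`, `beta_dep`, `beta_sub`, `beta_den_x_vel`,
#'   `beta_den_x_dep`, `beta_den_x_sub`, `beta_loc`, `beta_shell`.
#' @param sigma2 Named numeric vector over (a subset of) `sigma2_gamma`,
#'   `sigma2_eps`, `sigma2_omega` (variances, not sds).
#' @param gamma,eps,omega Latent effect vectors (lengths: number of sampling
#'   dates, number of females, number of population replicates).
#' @return A list of class `fert_params`.
#' @export
model_parameters <- function(design, fixed = NULL, sigma2 = NULL,
                             gamma = NULL, eps = NULL, omega = NULL) {
  fx <- setNames(numeric(length(FIXED_EFFECT_NAMES)), FIXED_EFFECT_NAMES)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), FIXED_EFFECT_NAMES)
    if (length(bad) > 0) {
      abort(paste("unknown fixed effects:", paste(bad, collapse = ", ")),
            class = "crypticallee_error_structural")
    }
    fx[names(fixed)] <- fixed
  }
  s2 <- setNames(numeric(3), SIGMA2_NAMES)
  if (!is.null(sigma2)) {
    bad <- setdiff(names(sigma2), SIGMA2_NAMES)
    if (length(bad) > 0) {
      abort(paste("unknown variance components:", paste(bad, collapse = ", ")),
            class = "crypticallee_error_structural")
    }
    s2[names(sigma2)] <- sigma2
  }
  K <- length(design$date_levels)
  N <- length(design$y)
  J <- length(design$pop_levels)
  gamma <- gamma %||% numeric(K)
  eps <- eps %||% numeric(N)
  omega <- omega %||% numeric(J)
  if (length(gamma) != K || length(eps) != N || length(omega) != J) {
    abort("latent effect vectors do not match the design's index sets",
          class = "crypticallee_error_structural")
  }
  structure(
    list(fixed = fx, sigma2 = s2, gamma = as.numeric(gamma),
         eps = as.numeric(eps), omega = as.numeric(omega)),
    class = "fert_params"
  )
}

#' Flatten / restore model parameters
#'
#' Serializes a `fert_params` to a flat named vector (`beta_den`,
#' `sigma2_eps`, `gamma[k]`, `eps[i]`, `omega[j]`, ...) and back; the flat
#' form is also the sampler's parameter layout.
#'
#' @param params A `fert_params`.
#' @param design The matching `fert_design` (needed to restore).
#' @param x A named numeric vector in the flat layout.
#' @return `as_param_vector()` a named numeric vector; `from_param_vector()`
#'   a `fert_params`.
#' @export
as_param_vector <- function(params) {
  c(params$fixed, params$sigma2,
    setNames(params$gamma, sprintf("gamma[%d]", seq_along(params$gamma))),
    setNames(params$eps, sprintf("eps[%d]", seq_along(params$eps))),
    setNames(params$omega, sprintf("omega[%d]", seq_along(params$omega))))
}

#' @rdname as_param_vector
#' @export
from_param_vector <- function(x, design) {
  K <- length(design$date_levels)
  N <- length(design$y)
  J <- length(design$pop_levels)
  model_parameters(
    design,
    fixed = x[FIXED_EFFECT_NAMES],
    sigma2 = x[SIGMA2_NAMES],
    gamma = unname(x[sprintf("gamma[%d]", seq_len(K))]),
    eps = unname(x[sprintf("eps[%d]", seq_len(N))]),
    omega = unname(x[sprintf("omega[%d]", seq_len(J))])
  )
}

#' Prior specification
#'
#' Vague priors: independent Normal(0, variance = `coef_variance`) on every
#' fixed effect and Uniform(0, `variance_upper`) on each variance component
#' (applied to the variance itself, not the sd).
#'
#' @param coef_variance Variance of the normal coefficient prior
#'   (default 100, i.e. sd 10).
#' @param variance_upper Upper bound of the uniform prior on each sigma^2
#'   (default 100).
#' @return A list of class `fert_prior`.
#' @export
prior_spec <- function(coef_variance = 100, variance_upper = 100) {
  stopifnot(coef_variance > 0, variance_upper > 0)
  structure(list(coef_variance = coef_variance, variance_upper = variance_upper),
            class = "fert_prior")
}

#' Linear predictor on the logit scale
#'
#' Substitutes the population-level submodel into the population intercept
#' and returns, per female, the full logit-scale predictor including the
#' latent date, overdispersion and population effects.
#'
#' @param design A `fert_design`.
#' @param params A `fert_params`.
#' @return Numeric vector, one value per female.
#' @export
linear_predictor <- function(design, params) {
  eta <- as.numeric(as.matrix(design$X) %*% params$fixed)
  eta + params$gamma[design$date_id] + params$eps + params$omega[design$pop_id]
}

#' Model log-densities
#'
#' `log_likelihood()` is the binomial log-likelihood (binomial coefficient
#' included, so values are absolute and comparable across implementations),
#' evaluated through a numerically stable log-inverse-logit so extreme logits
#' do not overflow; probabilities are clipped at 1e-12 from the boundary.
#' `log_prior()` sums the coefficient and variance priors plus the normal
#' log-densities of every latent effect given its variance component;
#' `log_posterior()` is their sum, with -Inf propagating.
#'
#' @inheritParams linear_predictor
#' @param prior A `fert_prior` (default [prior_spec()]).
#' @return A single numeric value.
#' @export
log_likelihood <- function(design, params) {
  y <- design$y
  n <- design$n
  if (any(y < 0 | y > n)) {
    abort("y outside [0, n]", class = "crypticallee_error_data")
  }
  eta <- linear_predictor(design, params)
  # log p = -log1p_exp(-eta), log(1-p) = -log1p_exp(eta); clip via bounded eta
  eta_c <- pmin(pmax(eta, logit(1e-12)), logit(1 - 1e-12))
  sum(lchoose(n, y) - y * log1p_exp(-eta_c) - (n - y) * log1p_exp(eta_c))
}

#' @rdname log_likelihood
#' @export
log_prior <- function(params, prior = prior_spec()) {
  s2 <- params$sigma2
  if (any(s2 <= 0) || any(s2 >= prior$variance_upper)) {
    return(-Inf)
  }
  lp <- sum(dnorm(params$fixed, 0, sqrt(prior$coef_variance), log = TRUE)) +
    -3 * log(prior$variance_upper)
  lp +
    sum(dnorm(params$gamma, 0, sqrt(s2[["sigma2_gamma"]]), log = TRUE)) +
    sum(dnorm(params$eps, 0, sqrt(s2[["sigma2_eps"]]), log = TRUE)) +
    sum(dnorm(params$omega, 0, sqrt(s2[["sigma2_omega"]]), log = TRUE))
}

#' @rdname log_likelihood
#' @export
log_posterior <- function(design, params, prior = prior_spec()) {
  lp <- log_prior(params, prior)
  if (!is.finite(lp)) {
    return(-Inf)
  }
  lp + log_likelihood(design, params)
}
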