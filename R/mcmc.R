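# Posterior sampling and summarization: chain configuration, the R-side
# driver around the compiled Metropolis-within-Gibbs core, split-chain R-hat,
# and posterior summary tables.

COEF_BY_COLUMN <- c(
  intercept = "alpha_global", p_den = "alpha_pden", cat = "alpha_cat",
  p_den_x_cat = "alpha_pden_x_cat", den = "beta_den", vel = "beta_vel",
  dep = "beta_dep", sub = "beta_sub", den_x_vel = "beta_den_x_vel",
  den_x_dep = "beta_den_x_dep", den_x_sub = "beta_den_x_sub",
  loc = "beta_loc", shell = "beta_shell"
)

#' MCMC configuration
#'
#' Chain settings for the Metropolis-within-Gibbs sampler. The defaults are
#' the reference analysis settings: 100 000 iterations, 20 000 burn-in, thin
#' 20, so each chain keeps 4000 draws; 3 chains are run from overdispersed
#' starting points.
#'
#' @param n_iterations Total iterations per chain.
#' @param n_burnin Burn-in iterations discarded (step sizes adapt only here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed controlling initial values and all proposals.
#' @param adapt_interval Iterations between step-size adaptations.
#' @param init_dispersion Sd multiplier for the overdispersed initial values.
#' @param init_step Initial random-walk step size for every parameter.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 100000, n_burnin = 20000, thin = 20,
                        n_chains = 3, seed = 1L, adapt_interval = 50,
                        init_dispersion = 2, init_step = 0.1) {
  stopifnot(n_burnin < n_iterations, thin >= 1, n_chains >= 1,
            adapt_interval >= 1, init_step > 0, init_dispersion >= 0)
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_burnin = as.integer(n_burnin), thin = as.integer(thin),
         n_chains = as.integer(n_chains), seed = as.integer(seed),
         adapt_interval = as.integer(adapt_interval),
         init_dispersion = init_dispersion, init_step = init_step),
    class = "mcmc_config"
  )
}

param_layout <- function(design, columns, include_gamma, include_eps,
                         include_omega) {
  K <- if (include_gamma) length(design$date_levels) else 0L
  N <- length(design$y)
  NE <- if (include_eps) N else 0L
  J <- if (include_omega) length(design$pop_levels) else 0L
  names <- c(
    unname(COEF_BY_COLUMN[columns]),
    SIGMA2_NAMES,
    if (K > 0) sprintf("gamma[%d]", seq_len(K)),
    if (NE > 0) sprintf("eps[%d]", seq_len(NE)),
    if (J > 0) sprintf("omega[%d]", seq_len(J))
  )
  list(K = K, NE = NE, J = J, names = names,
       n_fixed = length(columns), n_total = length(names))
}

#' Run MCMC chains
#'
#' Samples the joint posterior by adaptive random-walk Metropolis updates of
#' every scalar parameter (fixed effects, variance components on the
#' sigma^2 scale with reflection at the uniform-prior bounds, and all latent
#' effects). Step sizes adapt toward ~0.44 acceptance during burn-in only
#' and are frozen afterwards. Each chain starts from overdispersed initial
#' values; everything is reproducible from `config$seed`.
#'
#' @param design A `fert_design` from [build_design()].
#' @param prior A `fert_prior`.
#' @param config An [mcmc_config()].
#' @param columns Design columns to include as fixed effects (default all
#'   13); reduced sets give reduced submodels, e.g. `"intercept"` alone is a
#'   single-proportion model.
#' @param include_gamma,include_eps,include_omega Switch the three
#'   random-effect sets on or off.
#' @return An object of class `fert_fit`: list with `draws` (one matrix per
#'   chain, kept iterations x parameters, named columns), `design`, `prior`,
#'   `config`, `columns`, `include`, `sampler` (per-chain acceptance rates
#'   and frozen step sizes).
#' @export
run_chains <- function(design, prior = prior_spec(), config = mcmc_config(),
                       columns = names(design$X),
                       include_gamma = TRUE, include_eps = TRUE,
                       include_omega = TRUE) {
  stopifnot(inherits(design, "fert_design"))
  bad <- setdiff(columns, names(design$X))
  if (length(bad) > 0) {
    abort(paste("unknown design columns:", paste(bad, collapse = ", ")),
          class = "crypticallee_error_structural")
  }
  X <- as.matrix(design$X[, columns, drop = FALSE])
  lay <- param_layout(design, columns, include_gamma, include_eps,
                      include_omega)

  # columns constant within population / date groups admit compensated
  # (likelihood-invariant) recentering moves against the matching latents
  const_within <- function(id, n_groups) {
    keep <- integer(0)
    V <- matrix(0, n_groups, 0)
    for (m in seq_along(columns)) {
      v <- vapply(seq_len(n_groups), function(g) {
        vals <- unique(X[id == g, m])
        if (length(vals) == 1) vals else NA_real_
      }, numeric(1))
      if (!anyNA(v)) {
        keep <- c(keep, m - 1L)
        V <- cbind(V, v)
      }
    }
    list(cols = keep, V = V)
  }
  pop_comp <- if (include_omega) {
    const_within(design$pop_id, length(design$pop_levels))
  } else {
    list(cols = integer(0), V = matrix(0, max(lay$J, 1), 0))
  }
  date_comp <- if (include_gamma) {
    const_within(design$date_id, length(design$date_levels))
  } else {
    list(cols = integer(0), V = matrix(0, max(lay$K, 1), 0))
  }
  n_steps <- lay$n_total + length(pop_comp$cols) + length(date_comp$cols) +
    if (include_eps) lay$n_fixed else 0L

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  chains <- purrr::map(seq_len(config$n_chains), function(ch) {
    set.seed(chain_seeds[ch])
    init <- c(
      rnorm(lay$n_fixed, 0, config$init_dispersion),
      runif(3, 0.1, min(10, prior$variance_upper * 0.5)),
      rnorm(lay$K + lay$NE + lay$J, 0, 0.5)
    )
    out <- mwg_sampler(
      y = design$y, n = design$n, X = X,
      date_id = design$date_id, pop_id = design$pop_id,
      K = lay$K, J = lay$J, use_eps = lay$NE > 0,
      coef_var = prior$coef_variance, var_upper = prior$variance_upper,
      n_iter = config$n_iterations, n_burn = config$n_burnin,
      thin = config$thin,
      init = init,
      init_step = rep(config$init_step, n_steps),
      adapt_interval = config$adapt_interval,
      pop_cols = pop_comp$cols, Vpop = pop_comp$V,
      date_cols = date_comp$cols, Vdate = date_comp$V,
      eps_comp = include_eps
    )
    colnames(out$draws) <- lay$names
    out
  })

  structure(
    list(
      draws = purrr::map(chains, "draws"),
      sampler = purrr::map(chains, function(ch) {
        nm <- c(lay$names,
                if (length(pop_comp$cols) > 0)
                  paste0("comp_pop:", COEF_BY_COLUMN[columns][pop_comp$cols + 1]),
                if (length(date_comp$cols) > 0)
                  paste0("comp_date:", COEF_BY_COLUMN[columns][date_comp$cols + 1]),
                if (include_eps)
                  paste0("comp_eps:", COEF_BY_COLUMN[columns]))
        list(step_sizes = setNames(as.numeric(ch$step_sizes), nm),
             accept_rate = setNames(as.numeric(ch$accept_rate), nm))
      }),
      design = design, prior = prior, config = config,
      columns = columns,
      include = list(gamma = include_gamma, eps = include_eps,
                     omega = include_omega),
      layout = lay
    ),
    class = "fert_fit"
  )
}

#' Fit the hierarchical fertilization model
#'
#' End-to-end convenience wrapper: builds the standardized design from the
#' study tables and samples the full model's posterior.
#'
#' @inheritParams build_design
#' @inheritParams run_chains
#' @return A `fert_fit`; see [run_chains()].
#' @export
fit_fertilization_model <- function(females, populations,
                                    prior = prior_spec(),
                                    config = mcmc_config()) {
  design <- build_design(females, populations)
  run_chains(design, prior = prior, config = config)
}

#' @export
print.fert_fit <- function(x, ...) {
  cat(sprintf(
    "<fert_fit> %d chains x %d kept draws, %d parameters (%d fixed effects)\n",
    length(x$draws), nrow(x$draws[[1]]), x$layout$n_total, x$layout$n_fixed
  ))
  cat(sprintf("data: %d females, %d population replicates\n",
              length(x$design$y), length(x$design$pop_levels)))
  invisible(x)
}

#' Pooled posterior draws
#'
#' @param fit A `fert_fit`.
#' @param params Parameter names to keep (default: all).
#' @return A matrix, pooled kept draws x parameters.
#' @export
posterior_draws <- function(fit, params = NULL) {
  m <- do.call(rbind, fit$draws)
  if (!is.null(params)) m <- m[, params, drop = FALSE]
  m
}

#' Split-chain R-hat
#'
#' Gelman-Rubin potential scale reduction factor in the split-chain,
#' rank-normalized variant: each chain is halved, the pooled draws are
#' rank-transformed to normal scores, and the classic between/within
#' variance ratio is computed on the result. Constant draws return 1 by
#' convention.
#'
#' @param draws A matrix of draws for one parameter, iterations x chains, or
#'   a list of per-chain numeric vectors.
#' @return A single numeric value, >= 1 up to Monte-Carlo noise.
#' @export
rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) {
    abort("R-hat needs at least 2 chains", class = "crypticallee_error_diagnostic")
  }
  if (nrow(draws) < 10) {
    abort("R-hat needs at least 10 draws per chain",
          class = "crypticallee_error_diagnostic")
  }
  half <- floor(nrow(draws) / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[nrow(draws) - half + seq_len(half), , drop = FALSE])
  if (max(split) == min(split)) {
    return(1.0)
  }
  z <- qnorm((rank(split) - 3 / 8) / (length(split) + 1 / 4))
  z <- matrix(z, nrow = half)
  m <- ncol(z)
  n_it <- nrow(z)
  chain_means <- colMeans(z)
  b <- n_it * var(chain_means)
  w <- mean(apply(z, 2, var))
  if (w == 0) {
    return(1.0)
  }
  sqrt(((n_it - 1) / n_it * w + b / n_it) / w)
}

#' Posterior summary table
#'
#' Per parameter: median, central 95% credible interval (empirical 2.5/97.5
#' percentiles), sign probabilities (draws exactly 0 count as positive),
#' split-chain R-hat and the kept-draw count. A parameter is flagged
#' significant when its 95% interval excludes zero.
#'
#' @param fit A `fert_fit` (or a list of per-chain draw matrices with named
#'   columns).
#' @param params Parameters to summarize; default: fixed effects and
#'   variance components (latents omitted).
#' @return A tibble: `parameter`, `median`, `lower`, `upper`, `p_positive`,
#'   `p_negative`, `rhat`, `n_draws`, `significant`.
#' @export
summarize_draws <- function(fit, params = NULL) {
  chains <- if (inherits(fit, "fert_fit")) fit$draws else fit
  all_names <- colnames(chains[[1]])
  if (is.null(params)) {
    params <- all_names[!grepl("^(gamma|eps|omega)\\[", all_names)]
  }
  pooled <- do.call(rbind, chains)
  purrr::map_dfr(params, function(p) {
    x <- pooled[, p]
    q <- unname(quantile(x, c(0.025, 0.5, 0.975), type = 7))
    rh <- if (length(chains) >= 2) {
      rhat(purrr::map(chains, ~.x[, p]))
    } else {
      NA_real_
    }
    tibble::tibble(
      parameter = p, median = q[2], lower = q[1], upper = q[3],
      p_positive = mean(x >= 0), p_negative = mean(x < 0),
      rhat = rh, n_draws = length(x),
      significant = q[1] > 0 | q[3] < 0
    )
  })
}

#' @rdname summarize_draws
#' @param x A `fert_fit`.
#' @param ... Unused.
#' @export
tidy.fert_fit <- function(x, params = NULL, ...) {
  summarize_draws(x, params = params)
}

#' One-row fit overview
#'
#' @param x A `fert_fit`.
#' @param ... Unused.
#' @return A tibble with data sizes, draw counts and the worst R-hat over
#'   fixed effects and variance components.
#' @export
glance.fert_fit <- function(x, ...) {
  s <- summarize_draws(x)
  tibble::tibble(
    n_females = length(x$design$y),
    n_population_replicates = length(x$design$pop_levels),
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]) * length(x$draws),
    max_rhat = max(s$rhat),
    converged = max(s$rhat) <= 1.1
  )
}

#' Write / read posterior draws in long format
#'
#' Long CSV with columns `chain`, `iteration`, `parameter`, `value`.
#'
#' @param fit A `fert_fit`.
#' @param path CSV path.
#' @param params Parameters to keep (default: fixed effects + variance
#'   components).
#' @return The long tibble, invisibly for the writer.
#' @export
draws_long <- function(fit, params = NULL) {
  all_names <- colnames(fit$draws[[1]])
  if (is.null(params)) {
    params <- all_names[!grepl("^(gamma|eps|omega)\\[", all_names)]
  }
  purrr::imap_dfr(fit$draws, function(d, ch) {
    tibble::as_tibble(d[, params, drop = FALSE]) |>
      dplyr::mutate(chain = ch, iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter")
  }) |>
    dplyr::select("chain", "iteration", "parameter", "value")
}

#' @rdname draws_long
#' @export
write_draws_csv <- function(fit, path, params = NULL) {
  out <- draws_long(fit, params = params)
  readr::write_csv(out, path)
  invisible(out)
}
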