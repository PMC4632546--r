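# Posterior predictive goodness-of-fit: the Bayesian p-value compares a
# discrepancy between observed data and fitted probabilities against the
# same discrepancy on data replicated from the fitted model, draw by draw.

#' Per-draw linear predictors
#'
#' Reconstructs the logit-scale predictor of every record under every pooled
#' posterior draw, including the latent effects sampled with that draw.
#'
#' @param fit A `fert_fit`.
#' @return A matrix, records x pooled draws.
#' @export
posterior_eta <- function(fit) {
  design <- fit$design
  pooled <- posterior_draws(fit)
  fixed_names <- unname(COEF_BY_COLUMN[fit$columns])
  X <- as.matrix(design$X[, fit$columns, drop = FALSE])
  eta <- X %*% t(pooled[, fixed_names, drop = FALSE])
  if (fit$layout$K > 0) {
    g <- t(pooled[, sprintf("gamma[%d]", seq_len(fit$layout$K)), drop = FALSE])
    eta <- eta + g[design$date_id, , drop = FALSE]
  }
  if (fit$layout$NE > 0) {
    eta <- eta + t(pooled[, sprintf("eps[%d]", seq_len(fit$layout$NE)),
                          drop = FALSE])
  }
  if (fit$layout$J > 0) {
    w <- t(pooled[, sprintf("omega[%d]", seq_len(fit$layout$J)), drop = FALSE])
    eta <- eta + w[design$pop_id, , drop = FALSE]
  }
  eta
}

discrepancy_fun <- function(name) {
  switch(
    name,
    pearson_chi2 = function(y, n, p) sum((y - n * p)^2 / (n * p * (1 - p))),
    abs_residual = function(y, n, p) sum(abs(y - n * p)),
    deviance = function(y, n, p) {
      mu <- n * p
      term <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
      2 * sum(term(y, mu) + term(n - y, n - mu))
    },
    abort(paste("unknown discrepancy:", name),
          class = "crypticallee_error_configuration")
  )
}

#' Posterior predictive Bayesian p-value
#'
#' For each pooled posterior draw, computes the discrepancy between the
#' observed counts and that draw's fitted probabilities, simulates a
#' replicate dataset `y_rep ~ Binomial(n, p)` under the same probabilities,
#' and computes the replicate discrepancy. The Bayesian p-value is the
#' fraction of draws whose replicate discrepancy is at least the observed
#' one; values near 0.5 indicate adequate fit, values near 0 or 1 poor fit.
#'
#' @param fit A `fert_fit`.
#' @param discrepancy One of `"pearson_chi2"` (default; Pearson chi-square
#'   on binomial counts), `"abs_residual"`, `"deviance"`.
#' @param seed Integer seed for the replicate draws.
#' @return A list of class `fert_ppc`: `p_value`, `discrepancy`, and a
#'   tibble `draws` with per-draw `t_obs` and `t_rep`; `n_clipped` counts
#'   fitted probabilities clipped away from \{0, 1\}.
#' @export
bayesian_p_value <- function(fit, discrepancy = "pearson_chi2", seed = 1) {
  set.seed(seed)
  fun <- discrepancy_fun(discrepancy)
  eta <- posterior_eta(fit)
  y <- fit$design$y
  n <- fit$design$n
  p_all <- inv_logit(eta)
  n_clipped <- sum(p_all <= 1e-12 | p_all >= 1 - 1e-12)
  S <- ncol(eta)
  t_obs <- numeric(S)
  t_rep <- numeric(S)
  for (s in seq_len(S)) {
    p <- clip_p(p_all[, s])
    t_obs[s] <- fun(y, n, p)
    y_rep <- rbinom(length(p), n, p)
    t_rep[s] <- fun(y_rep, n, p)
  }
  structure(
    list(
      p_value = mean(t_rep >= t_obs),
      discrepancy = discrepancy,
      draws = tibble::tibble(draw = seq_len(S), t_obs = t_obs, t_rep = t_rep),
      n_clipped = n_clipped
    ),
    class = "fert_ppc"
  )
}

#' @export
print.fert_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%s): Bayesian p-value = %.3f\n",
              x$discrepancy, x$p_value))
  if (x$n_clipped > 0) {
    cat(sprintf("note: %d fitted probabilities clipped at the boundary\n",
                x$n_clipped))
  }
  invisible(x)
}

#' @rdname bayesian_p_value
#' @param x A `fert_ppc`.
#' @param ... Unused.
#' @export
tidy.fert_ppc <- function(x, ...) {
  tibble::tibble(discrepancy = x$discrepancy, p_value = x$p_value,
                 mean_t_obs = mean(x$draws$t_obs),
                 mean_t_rep = mean(x$draws$t_rep))
}

#' @rdname bayesian_p_value
#' @param object A `fert_ppc`.
#' @export
autoplot.fert_ppc <- function(object, ...) {
  lim <- range(object$draws$t_obs, object$draws$t_rep)
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$t_obs, y = .data$t_rep)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(
      x = "discrepancy, observed data",
      y = "discrepancy, replicated data",
      title = sprintf("Bayesian p-value = %.2f (%s)", object$p_value,
                      object$discrepancy)
    ) +
    ggplot2::theme_minimal()
}
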