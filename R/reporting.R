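# Reporting: the effect table with sign probabilities, caterpillar plot,
# and percentile-conditioned prediction curves over local density.

#' Effect table
#'
#' All 13 fixed effects of the model - the population level (mean population
#' density, catchment area, their interaction) and the local level (density,
#' flow covariates, interactions, location, shell length) - with posterior
#' median, 95% credible interval, the probability of the dominant sign, and
#' a significance flag (interval excludes zero).
#'
#' @param fit A `fert_fit`, or a posterior summary tibble from
#'   [summarize_draws()].
#' @return A tibble with columns `parameter`, `level`, `median`, `lower`,
#'   `upper`, `p_sign` (probability of the dominant sign), `sign`,
#'   `significant`.
#' @export
effect_table <- function(fit) {
  s <- if (inherits(fit, "fert_fit")) summarize_draws(fit) else fit
  s <- dplyr::filter(s, .data$parameter %in% FIXED_EFFECT_NAMES)
  s |>
    dplyr::mutate(
      level = dplyr::if_else(grepl("^alpha", .data$parameter),
                             "population", "local"),
      sign = dplyr::if_else(.data$p_positive >= .data$p_negative,
                            "positive", "negative"),
      p_sign = pmax(.data$p_positive, .data$p_negative),
      parameter = factor(.data$parameter, levels = FIXED_EFFECT_NAMES)
    ) |>
    dplyr::arrange(.data$parameter) |>
    dplyr::mutate(parameter = as.character(.data$parameter)) |>
    dplyr::select("parameter", "level", "median", "lower", "upper",
                  "p_sign", "sign", "significant")
}

#' Caterpillar plot of the fixed effects
#'
#' Medians and 95% credible intervals for the 13 fixed effects, split by
#' level; effects whose interval excludes zero are highlighted.
#'
#' @param object A `fert_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fert_fit <- function(object, ...) {
  et <- effect_table(object) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(FIXED_EFFECT_NAMES)))
  ggplot2::ggplot(et, ggplot2::aes(x = .data$median, y = .data$parameter,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red3")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$level), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "posterior median and 95% CrI (standardized scale)",
                  y = NULL, colour = "95% CrI excludes 0") +
    ggplot2::theme_minimal()
}

#' Percentile-conditioned prediction curves
#'
#' Predicted fertilization rate over a grid of local conspecific density,
#' conditioned at the dataset's empirical 25th and 75th percentiles of a
#' flow covariate (current velocity or water depth). All other covariates
#' are held at their means (standardized 0) and latent effects at 0, giving
#' a population-average curve; per grid point the pointwise median and
#' central 95-percentile band over posterior draws are returned, with the
#' density axis back-transformed to natural units.
#'
#' @param fit A `fert_fit`.
#' @param cond_vars Conditioning covariates (default velocity and depth).
#' @param probs Conditioning percentiles (default 25th and 75th).
#' @param den_grid Grid of local density values in natural units (default:
#'   50 points over the observed range).
#' @param draws Optional draw matrix overriding the fit's pooled draws
#'   (columns named like the fixed effects); useful for plotting known
#'   parameter sets.
#' @return A tibble: `cond_var`, `cond_prob`, `cond_value` (natural units),
#'   `den`, `p_median`, `p_lower`, `p_upper`.
#' @export
predict_fertilization_curve <- function(fit, cond_vars = c("vel", "dep"),
                                        probs = c(0.25, 0.75),
                                        den_grid = NULL, draws = NULL) {
  design <- fit$design
  spec <- design$spec
  if (is.null(draws)) draws <- posterior_draws(fit)
  if (nrow(draws) == 0) {
    abort("no posterior draws available", class = "crypticallee_error_validation")
  }
  if (is.null(den_grid)) {
    den_grid <- seq(min(design$females$den), max(design$females$den),
                    length.out = 50)
  }
  den_z <- standardize_value(spec, "den", den_grid)
  b_den <- draws[, "beta_den"]
  a0 <- draws[, "alpha_global"]

  purrr::map_dfr(cond_vars, function(v) {
    inter <- paste0("beta_den_x_", v)
    b_v <- draws[, paste0("beta_", v)]
    b_int <- if (inter %in% colnames(draws)) draws[, inter] else 0
    purrr::map_dfr(probs, function(q) {
      val <- unname(quantile(design$females[[v]], q, type = 7))
      z_v <- standardize_value(spec, v, val)
      purrr::map_dfr(seq_along(den_grid), function(g) {
        eta <- a0 + b_den * den_z[g] + b_v * z_v + b_int * den_z[g] * z_v
        p <- inv_logit(eta)
        qs <- unname(quantile(p, c(0.025, 0.5, 0.975), type = 7))
        tibble::tibble(
          cond_var = v, cond_prob = q, cond_value = val,
          den = den_grid[g],
          p_median = qs[2], p_lower = qs[1], p_upper = qs[3]
        )
      })
    })
  })
}

#' Interaction prediction panels
#'
#' Four panels of predicted fertilization rate against local density: at
#' the 25th and 75th percentile of current velocity, and of water depth
#' (median curve plus 95-percentile band); observed per-female rates
#' overlaid.
#'
#' @param fit A `fert_fit`.
#' @inheritParams predict_fertilization_curve
#' @return A ggplot.
#' @export
plot_interaction_panels <- function(fit, probs = c(0.25, 0.75),
                                    den_grid = NULL, draws = NULL) {
  curves <- predict_fertilization_curve(fit, cond_vars = c("vel", "dep"),
                                        probs = probs, den_grid = den_grid,
                                        draws = draws) |>
    dplyr::mutate(panel = sprintf("%s at %gth percentile (%.1f)",
                                  .data$cond_var, 100 * .data$cond_prob,
                                  .data$cond_value))
  obs <- tibble::tibble(den = fit$design$females$den,
                        rate = fit$design$y / fit$design$n)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$den)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$rate),
                        colour = "grey55", alpha = 0.6, size = 0.8) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p_lower,
                                      ymax = .data$p_upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_median),
                       colour = "steelblue4") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), nrow = 2) +
    ggplot2::labs(x = "local conspecific density (ind. / 0.25 m²)",
                  y = "fertilization rate") +
    ggplot2::theme_minimal()
}
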