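# Standardization and assembly of the model design: z-scored covariates,
# cross-level interaction columns, and the index sets for the random effects.

LOCAL_COVARIATES <- c("den", "vel", "dep", "sub", "loc", "shell")
POPULATION_COVARIATES <- c("p_den", "cat")
FIXED_EFFECT_NAMES <- c(
  "alpha_global", "alpha_pden", "alpha_cat", "alpha_pden_x_cat",
  "beta_den", "beta_vel", "beta_dep", "beta_sub",
  "beta_den_x_vel", "beta_den_x_dep", "beta_den_x_sub",
  "beta_loc", "beta_shell"
)

z_score <- function(x, mu, s) (x - mu) / s

#' Build the standardized model design
#'
#' Joins population attributes onto the usable per-female records, z-scores
#' all eight covariates (sample mean/sd, n-1 denominator), forms the four
#' interaction columns as products of the already-standardized mains
#' (den x vel, den x dep, den x sub, p_den x cat), and indexes the three
#' random-effect sets: sampling date nested in year, per-female
#' overdispersion, and population x year replicate.
#'
#' Local covariates are standardized over the female rows; the two
#' population-level covariates are standardized over the distinct
#' population x year replicates, so their coefficients are per population-sd
#' rather than weighted by sample size.
#'
#' @param females A data frame of per-female records: `female_id`,
#'   `population_id`, `date`, `year`, `y`, `n`, `den`, `vel`, `dep`, `sub`,
#'   `loc`, `shell` and optionally `usable`. Missing covariate cells are
#'   rejected, not imputed.
#' @param populations A data frame with `population_id`, `year`, `p_den`,
#'   `cat`, one row per population x year replicate.
#' @return An object of class `fert_design`: a list with
#' \describe{
#'   \item{X}{tibble of the 13 fixed-effect columns (intercept first).}
#'   \item{y, n}{integer response vectors.}
#'   \item{date_id, pop_id}{1-based indices into the date and population
#'     random-effect sets.}
#'   \item{date_levels, pop_levels}{labels, `"date|year"` and
#'     `"population_id|year"`.}
#'   \item{spec}{the standardization spec: tibble `covariate`, `mean`, `sd`,
#'     `level`.}
#'   \item{females}{the usable records after the population join.}
#' }
#' @export
build_design <- function(females, populations) {
  females <- filter_usable(tibble::as_tibble(females))
  populations <- tibble::as_tibble(populations)

  need_f <- c("female_id", "population_id", "date", "year", "y", "n",
              LOCAL_COVARIATES)
  need_p <- c("population_id", "year", POPULATION_COVARIATES)
  miss <- c(setdiff(need_f, names(females)), setdiff(need_p, names(populations)))
  if (length(miss) > 0) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
          class = "crypticallee_error_validation")
  }
  if (any(females$y < 0 | females$y > females$n)) {
    abort("y must satisfy 0 <= y <= n", class = "crypticallee_error_validation")
  }

  dat <- dplyr::inner_join(females, populations,
                           by = c("population_id", "year"))
  if (nrow(dat) < nrow(females)) {
    abort("some females reference a population x year absent from `populations`",
          class = "crypticallee_error_missing_population")
  }
  all_cov <- c(LOCAL_COVARIATES, POPULATION_COVARIATES)
  if (anyNA(dat[all_cov])) {
    abort("missing covariate cells are not allowed",
          class = "crypticallee_error_validation")
  }

  spec_local <- purrr::map_dfr(LOCAL_COVARIATES, function(v) {
    tibble::tibble(covariate = v, mean = mean(dat[[v]]), sd = sd(dat[[v]]),
                   level = "local")
  })
  pops_used <- dplyr::semi_join(populations, dat, by = c("population_id", "year"))
  spec_pop <- purrr::map_dfr(POPULATION_COVARIATES, function(v) {
    tibble::tibble(covariate = v, mean = mean(pops_used[[v]]),
                   sd = sd(pops_used[[v]]), level = "population")
  })
  spec <- dplyr::bind_rows(spec_local, spec_pop)
  if (any(!is.finite(spec$sd) | spec$sd <= 0)) {
    bad <- spec$covariate[!is.finite(spec$sd) | spec$sd <= 0]
    abort(paste("zero-variance covariate(s):", paste(bad, collapse = ", ")),
          class = "crypticallee_error_degenerate_covariate")
  }

  z <- purrr::map(setNames(spec$covariate, spec$covariate), function(v) {
    row <- spec[spec$covariate == v, ]
    z_score(dat[[v]], row$mean, row$sd)
  })
  X <- tibble::tibble(
    intercept = rep(1, nrow(dat)),
    p_den = z$p_den, cat = z$cat, p_den_x_cat = z$p_den * z$cat,
    den = z$den, vel = z$vel, dep = z$dep, sub = z$sub,
    den_x_vel = z$den * z$vel, den_x_dep = z$den * z$dep,
    den_x_sub = z$den * z$sub,
    loc = z$loc, shell = z$shell
  )

  date_key <- paste(dat$date, dat$year, sep = "|")
  pop_key <- paste(dat$population_id, dat$year, sep = "|")
  date_levels <- unique(date_key)
  pop_levels <- unique(pop_key)

  structure(
    list(
      X = X,
      y = as.integer(dat$y), n = as.integer(dat$n),
      date_id = match(date_key, date_levels),
      pop_id = match(pop_key, pop_levels),
      date_levels = date_levels, pop_levels = pop_levels,
      spec = spec,
      females = dat
    ),
    class = "fert_design"
  )
}

#' @export
print.fert_design <- function(x, ...) {
  cat(sprintf(
    "<fert_design> %d females, %d population replicates, %d sampling dates\n",
    length(x$y), length(x$pop_levels), length(x$date_levels)
  ))
  cat("fixed-effect columns:", paste(names(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Map values between natural and standardized scales
#'
#' Uses the standardization spec stored in a design to move a covariate's
#' values onto the standardized (z) scale or back; used to condition and
#' back-transform prediction axes.
#'
#' @param spec A standardization spec tibble (`design$spec`) or a
#'   `fert_design`.
#' @param covariate Covariate name, e.g. `"den"`.
#' @param value Numeric values to transform.
#' @return Numeric vector of transformed values.
#' @export
standardize_value <- function(spec, covariate, value) {
  row <- spec_row(spec, covariate)
  (value - row$mean) / row$sd
}

#' @rdname standardize_value
#' @export
unstandardize_value <- function(spec, covariate, value) {
  row <- spec_row(spec, covariate)
  value * row$sd + row$mean
}

spec_row <- function(spec, covariate) {
  if (inherits(spec, "fert_design")) spec <- spec$spec
  row <- spec[spec$covariate == covariate, ]
  if (nrow(row) != 1) {
    abort(paste("unknown covariate:", covariate),
          class = "crypticallee_error_validation")
  }
  row
}

#' Validate a study dataset
#'
#' Checks the per-female and per-population tables, reports record counts,
#' per-level covariate summaries (mean, sd, range) and the correlation
#' screen.
#'
#' @inheritParams build_design
#' @param quiet Suppress printing.
#' @return Invisibly, a list with `n_collected`, `n_usable`, `summary`
#'   (tibble), and `screen` (the [correlation_screen()] result).
#' @export
validate_study_data <- function(females, populations, quiet = FALSE) {
  females <- tibble::as_tibble(females)
  design <- build_design(females, populations)
  dat <- design$females
  summarise_cov <- function(df, v, level) {
    tibble::tibble(
      level = level, covariate = v, mean = mean(df[[v]]), sd = sd(df[[v]]),
      min = min(df[[v]]), max = max(df[[v]])
    )
  }
  pops_used <- dplyr::distinct(dat, .data$population_id, .data$year,
                               .data$p_den, .data$cat)
  summary <- dplyr::bind_rows(
    purrr::map_dfr(POPULATION_COVARIATES, ~summarise_cov(pops_used, .x, "population")),
    purrr::map_dfr(LOCAL_COVARIATES, ~summarise_cov(dat, .x, "local"))
  )
  screen <- correlation_screen(tibble::as_tibble(
    dat[c(LOCAL_COVARIATES, POPULATION_COVARIATES)]
  ))
  out <- list(
    n_collected = nrow(females),
    n_usable = nrow(dat),
    n_population_replicates = length(design$pop_levels),
    summary = summary,
    screen = screen
  )
  if (!quiet) {
    cat(sprintf("%d females collected, %d usable, %d population replicates\n",
                out$n_collected, out$n_usable, out$n_population_replicates))
    print(summary, n = Inf)
    print(screen)
  }
  invisible(out)
}
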