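# Fertilization-count tallying, substrate index, record filtering and
# population-level density: the bookkeeping between raw field records and the
# model's design matrix.

#' Tally fertilized units per gravid female
#'
#' Egg samples are scored in replicate counts that each stop at exactly 100
#' units (developing glochidia + fertilized eggs + unfertilized eggs). The
#' response for one female is the number of fertilized units (fertilized eggs
#' plus glochidia) out of the total units counted across replicates; with the
#' standard three replicates the denominator is 300.
#'
#' @param egg_counts A data frame with one row per counting replicate and
#'   columns `female_id`, `n_fertilized`, `n_glochidia`, `n_unfertilized`.
#' @return A tibble with one row per female: `female_id`, `y` (fertilized
#'   units), `n` (total units = 100 x number of replicates).
#' @examples
#' reps <- tibble::tibble(
#'   female_id = rep("f1", 3),
#'   n_fertilized = c(40, 40, 40), n_glochidia = c(10, 10, 10),
#'   n_unfertilized = c(50, 50, 50)
#' )
#' tally_fertilization(reps) # y = 150, n = 300
#' @export
tally_fertilization <- function(egg_counts) {
  egg_counts <- tibble::as_tibble(egg_counts)
  need <- c("female_id", "n_fertilized", "n_glochidia", "n_unfertilized")
  missing_cols <- setdiff(need, names(egg_counts))
  if (length(missing_cols) > 0) {
    abort(paste("egg_counts lacks columns:", paste(missing_cols, collapse = ", ")),
          class = "crypticallee_error_malformed_count")
  }
  counts <- egg_counts[c("n_fertilized", "n_glochidia", "n_unfertilized")]
  if (any(vapply(counts, function(x) any(x < 0 | x != round(x)), logical(1)))) {
    abort("egg counts must be non-negative integers",
          class = "crypticallee_error_malformed_count")
  }
  tot <- egg_counts$n_fertilized + egg_counts$n_glochidia + egg_counts$n_unfertilized
  if (any(tot != 100)) {
    abort("each counting replicate must sum to exactly 100 units",
          class = "crypticallee_error_malformed_count")
  }
  egg_counts |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(
      y = sum(.data$n_fertilized + .data$n_glochidia),
      n = 100L * dplyr::n(),
      .groups = "drop"
    )
}

#' Substrate coarseness index
#'
#' Visual substrate composition is scored as proportions of four categories
#' coded sand = 1, gravel = 2, cobble = 3, boulder = 4; the coarseness index
#' is the code-weighted sum, a dimensionless value in \[1, 4\].
#'
#' @param composition A data frame with columns `sand`, `gravel`, `cobble`,
#'   `boulder`, each a proportion in \[0, 1\]; each row must sum to 1.
#' @return The input as a tibble with a `sub` column appended.
#' @examples
#' substrate_coarseness(tibble::tibble(
#'   sand = 0, gravel = 0.5, cobble = 0.5, boulder = 0
#' ))$sub # 2.5
#' @export
substrate_coarseness <- function(composition) {
  composition <- tibble::as_tibble(composition)
  cats <- c("sand", "gravel", "cobble", "boulder")
  missing_cols <- setdiff(cats, names(composition))
  if (length(missing_cols) > 0) {
    abort(paste("composition lacks columns:", paste(missing_cols, collapse = ", ")),
          class = "crypticallee_error_validation")
  }
  pm <- as.matrix(composition[cats])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9)) {
    abort("substrate proportions must be non-negative and sum to 1 per row",
          class = "crypticallee_error_validation")
  }
  composition$sub <- as.numeric(pm %*% 1:4)
  composition
}

#' Drop females whose eggs could not be scored
#'
#' Records where fertilized and unfertilized eggs could not be discriminated
#' carry `usable = FALSE` and are excluded from analysis; order is preserved.
#'
#' @param females A data frame of per-female records with a logical `usable`
#'   column (rows without the column are treated as usable).
#' @return A tibble containing exactly the usable rows, in input order.
#' @export
filter_usable <- function(females) {
  females <- tibble::as_tibble(females)
  if (!"usable" %in% names(females)) {
    return(females)
  }
  dplyr::filter(females, .data$usable)
}

#' Mean population density from local quadrat counts
#'
#' Population-level conspecific density for each population x year replicate
#' is the arithmetic mean of the local adult densities (individuals per
#' 0.25 m^2 quadrat) over that replicate's usable females.
#'
#' @param females A data frame of per-female records with columns
#'   `population_id`, `year`, `den` (and optionally `usable`).
#' @return A tibble with columns `population_id`, `year`, `p_den`.
#' @export
derive_population_density <- function(females) {
  usable <- filter_usable(females)
  if (nrow(usable) == 0) {
    abort("no usable records from which to derive population density",
          class = "crypticallee_error_missing_population")
  }
  usable |>
    dplyr::group_by(.data$population_id, .data$year) |>
    dplyr::summarise(p_den = mean(.data$den), .groups = "drop")
}

#' Pairwise-correlation screen of the explanatory variables
#'
#' Computes Pearson correlations among the eight main covariates (den, vel,
#' dep, sub, loc, shell, p_den, cat). The screen passes when every
#' off-diagonal |r| is below the threshold, the standard collinearity check
#' before fitting the full model.
#'
#' @param design A `fert_design` (see [build_design()]) or a data frame
#'   containing the eight covariate columns.
#' @param threshold Absolute correlation above which the screen fails
#'   (default 0.5).
#' @return A tibble of class `fert_corr_screen` with one row per unordered
#'   pair: `var1`, `var2`, `r`, plus attributes `pass` (logical) and
#'   `threshold`.
#' @export
correlation_screen <- function(design, threshold = 0.5) {
  covs <- c("den", "vel", "dep", "sub", "loc", "shell", "p_den", "cat")
  x <- if (inherits(design, "fert_design")) design$X else tibble::as_tibble(design)
  x <- x[intersect(covs, names(x))]
  if (nrow(x) < 3) {
    abort("correlation screen needs at least 3 rows",
          class = "crypticallee_error_validation")
  }
  cm <- cor(as.matrix(x))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = colnames(cm)[idx[, 1]],
    var2 = colnames(cm)[idx[, 2]],
    r = cm[idx]
  )
  attr(out, "pass") <- all(abs(out$r) < threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("fert_corr_screen", class(out))
  out
}

#' @export
print.fert_corr_screen <- function(x, ...) {
  cat(sprintf(
    "Correlation screen (|r| < %.2f): %s, max |r| = %.3f\n",
    attr(x, "threshold"), if (attr(x, "pass")) "PASS" else "FAIL",
    max(abs(x$r))
  ))
  NextMethod()
  invisible(x)
}
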