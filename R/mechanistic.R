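# Mechanistic sperm-dilution scene: males in each sampled quadrat act as
# sperm sources whose influence decays exponentially with distance (along
# the flow and across the channel); the decay length grows with current
# velocity and depth, and locally released sperm is further diluted by the
# water flux, so a female's exposure tracks her own patch's density only
# where flow is slow and shallow. Per-male output is normalized by the
# bed's mean density (filter-feeding competition for seston), which makes
# exposure a function of *relative* local density: population mean density
# then carries almost no information about population mean fertilization.
# This is the generator behind the "cryptic" scenario - a real local
# fitness-density relationship invisible at the population scale.

#' Default mechanistic constants
#'
#' Constants of the dilution scene, deliberately synthetic (no field values
#' exist for them):
#' \describe{
#'   \item{lambda0, a, b, vel_ref, dep_ref}{decay length
#'     `lambda = lambda0 * (1 + a*vel/vel_ref) * (1 + b*dep/dep_ref)` (m),
#'     referenced at the observed covariate means (16.5 cm/s, 29.7 cm).}
#'   \item{k_half, hill_exp}{exposure-to-probability map
#'     `p = E^h / (E^h + k_half^h)` (saturating, Michaelis-type at
#'     `hill_exp = 1`).}
#'   \item{sex_ratio}{fraction of adults that are male (1:1 observed).}
#'   \item{strip_quadrats}{bed strip represented by one transect's male
#'     cluster, in 0.25 m^2 quadrats' worth of the local density.}
#'   \item{dil_vel_ref, dil_dep_ref}{advective dilution of locally released
#'     sperm: local exposure is divided by
#'     `(1 + vel/dil_vel_ref) * (1 + dep/dil_dep_ref)`, the growth of the
#'     diluting water flux with velocity and depth.}
#'   \item{output_scale, density_cost_exp}{per-male sperm output
#'     `output_scale / p_den^density_cost_exp`: filter-feeding competition
#'     for seston in dense beds reduces per-male gamete output, so exposure
#'     tracks a female's density relative to her bed's mean, not the bed's
#'     absolute density.}
#'   \item{spawn_sdlog}{sd (log scale) of an optional per-replicate
#'     spawning-synchrony multiplier (off by default).}
#'   \item{bg_scale, bg_meanlog, bg_sdlog, bg_vel_ref, bg_vel_exp,
#'     bg_dep_exp, bg_filter}{optional flow-delivered background sperm
#'     supply from upstream sources (lognormal per population, delivered
#'     `~ (vel/bg_vel_ref)^bg_vel_exp * (dep/dep_ref)^bg_dep_exp`,
#'     attenuated `exp(-bg_filter * mean density)` by the bed's own
#'     filtering); `bg_scale = 0` disables it, the default.}
#' }
#'
#' @return A named list.
#' @export
default_mechanistic_constants <- function() {
  list(lambda0 = 0.5, a = 2, b = 2, vel_ref = 16.5, dep_ref = 29.7,
       k_half = 40, sex_ratio = 0.5, strip_quadrats = 8,
       hill_exp = 1, output_scale = 10, density_cost_exp = 1, spawn_sdlog = 0,
       dil_vel_ref = 8, dil_dep_ref = 120,
       bg_scale = 0, bg_meanlog = log(2000), bg_sdlog = 1.5,
       bg_vel_ref = 25, bg_vel_exp = 4, bg_dep_exp = 0,
       bg_filter = 0, local_filter = 0)
}

#' Dilution length-scale
#'
#' `lambda = lambda0 * (1 + a*vel/vel_ref) * (1 + b*dep/dep_ref)`; strictly
#' increasing in both velocity and depth.
#'
#' @param vel,dep Current velocity (cm/s) and water depth (cm).
#' @param constants See [default_mechanistic_constants()].
#' @return Numeric vector of decay lengths in metres.
#' @export
dilution_lambda <- function(vel, dep, constants = default_mechanistic_constants()) {
  constants$lambda0 * (1 + constants$a * vel / constants$vel_ref) *
    (1 + constants$b * dep / constants$dep_ref)
}

#' Sperm exposure along a reach
#'
#' For each receiving female, exposure is the kernel-weighted sum over male
#' groups: `E = sum_m count_m * exp(-|pos_f - pos_m| / lambda_f)`, with the
#' decay length evaluated at the female's own flow conditions. Additive over
#' disjoint male sets and invariant to male relabeling.
#'
#' @param receivers A data frame with columns `pos` (m along reach) and
#'   `lambda` (m).
#' @param males A data frame with columns `pos` and `count` (males at that
#'   position).
#' @return Numeric exposure per receiver (nonnegative; 0 when no males).
#' @export
sperm_exposure <- function(receivers, males) {
  if (nrow(males) == 0) {
    return(numeric(nrow(receivers)))
  }
  lat_r <- receivers$lateral %||% rep(0, nrow(receivers))
  lat_m <- males$lateral %||% rep(0, nrow(males))
  vapply(seq_len(nrow(receivers)), function(i) {
    d <- sqrt((receivers$pos[i] - males$pos)^2 + (lat_r[i] - lat_m)^2)
    sum(males$count * exp(-d / receivers$lambda[i]))
  }, numeric(1))
}

#' Build a mechanistic scene from drawn covariates
#'
#' Constructs, per population replicate, the male field implied by the
#' drawn quadrat densities: one male group per sampled quadrat holding
#' `round(sex_ratio * strip_quadrats * den)` males (the patch's bed strip
#' under a 1:1 sex ratio), positioned along the flow and across the
#' channel. Each female's dilution length follows from her local flow
#' conditions; her exposure is the kernel sum over the replicate's male
#' groups, scaled by the density-normalized per-male output and divided by
#' the advective dilution of her patch, plus any background supply.
#' Exposure maps to the true fertilization probability through the
#' saturating response `p = E^h / (E^h + k_half^h)`.
#'
#' @param cov Result of [draw_covariates()].
#' @param constants See [default_mechanistic_constants()].
#' @param seed Integer seed (background supplies are random).
#' @return A list of class `fert_scene`: `females` (covariates plus `pos`,
#'   `lambda`, `exposure`, `background`, `p_true`), `populations`, `males`
#'   (per-transect clusters), `constants`.
#' @export
build_mechanistic_scene <- function(cov, constants = default_mechanistic_constants(),
                                    seed = 1) {
  set.seed(seed)
  females <- cov$females
  females$pos <- cov$layout$loc
  females$transect <- cov$layout$transect
  females$transect_pos <- cov$layout$transect_pos
  females$lateral <- cov$layout$lateral %||% rep(0, nrow(females))
  females$lambda <- dilution_lambda(females$vel, females$dep, constants)

  reps <- dplyr::distinct(females, .data$population_id, .data$year)
  rep_key <- paste(reps$population_id, reps$year, sep = "|")
  bg_supply <- setNames(
    exp(rnorm(nrow(reps), constants$bg_meanlog, constants$bg_sdlog)), rep_key
  )
  # spawning-synchrony multiplier: how much of the males' sperm release
  # overlapped the brooding females' receptive window in this replicate
  spawn_sync <- setNames(
    exp(rnorm(nrow(reps), 0, constants$spawn_sdlog)), rep_key
  )

  males_all <- list()
  females <- females |>
    dplyr::group_by(.data$population_id, .data$year) |>
    dplyr::group_modify(function(df, key) {
      # one male group per sampled quadrat: the males sharing each female's
      # patch under a 1:1 sex ratio, scaled to the patch's bed strip
      males <- tibble::tibble(
        pos = df$pos,
        lateral = df$lateral,
        count = round(constants$sex_ratio * constants$strip_quadrats * df$den)
      )
      kk <- paste(key$population_id, key$year, sep = "|")
      males_all[[kk]] <<- males
      per_male_output <- spawn_sync[[kk]] * constants$output_scale *
        exp(-constants$local_filter * mean(df$den)) /
        max(mean(df$den), 0.5)^constants$density_cost_exp
      # advective dilution: the same local sperm release is spread through a
      # larger water flux at higher velocity and depth
      dilution <- (1 + df$vel / constants$dil_vel_ref) *
        (1 + df$dep / constants$dil_dep_ref)
      df$exposure_local <- per_male_output / dilution * sperm_exposure(
        tibble::tibble(pos = df$pos, lateral = df$lateral,
                       lambda = df$lambda), males
      )
      # the bed itself filters incoming water: dense beds strip background
      # sperm from the water column before it reaches a brooding female
      bg <- constants$bg_scale *
        bg_supply[[paste(key$population_id, key$year, sep = "|")]] *
        exp(-constants$bg_filter * mean(df$den))
      df$background <- bg *
        (df$vel / constants$bg_vel_ref)^constants$bg_vel_exp *
        (df$dep / constants$dep_ref)^constants$bg_dep_exp
      df
    }) |>
    dplyr::ungroup()
  females$exposure <- females$exposure_local + females$background
  eh <- females$exposure^constants$hill_exp
  females$p_true <- eh / (eh + constants$k_half^constants$hill_exp)
  structure(
    list(females = females, populations = cov$populations,
         males = males_all, constants = constants),
    class = "fert_scene"
  )
}

#' Simulate outcomes from a mechanistic scene
#'
#' Draws `y ~ Binomial(n, p_true)` per female from the scene's true
#' exposure-derived probabilities.
#'
#' @param scene A `fert_scene` from [build_mechanistic_scene()].
#' @param seed Integer seed.
#' @return A list `females` (study-table columns, `y` filled in),
#'   `populations`, `truth` (per-female `exposure`, `background`, `lambda`,
#'   `p`, and the scene constants).
#' @export
simulate_outcomes_mechanistic <- function(scene, seed = 1) {
  set.seed(seed)
  females <- scene$females
  females$y <- as.integer(rbinom(nrow(females), females$n, females$p_true))
  study_cols <- c("female_id", "population_id", "date", "year", "y", "n",
                  "den", "vel", "dep", "sub", "loc", "shell", "usable")
  list(
    females = females[study_cols],
    populations = scene$populations,
    truth = list(
      exposure = females$exposure, background = females$background,
      lambda = females$lambda, p = females$p_true,
      constants = scene$constants
    )
  )
}

#' Generate the cryptic Allee-effect dataset
#'
#' Convenience wrapper for the mechanistic scenario: by construction, local
#' quadrat density predicts fertilization where flow is slow and shallow,
#' while mean population density carries almost no signal about population
#' mean fertilization - the pattern a population-scale analysis would miss.
#'
#' @param scenario A [study_scenario()] with `flavor = "mechanistic"`.
#' @param seed Integer seed.
#' @return As [simulate_study()].
#' @export
make_cryptic_dataset <- function(scenario = study_scenario(flavor = "mechanistic"),
                                 seed = 1) {
  if (scenario$flavor != "mechanistic") {
    abort("make_cryptic_dataset() needs a mechanistic-flavor scenario",
          class = "crypticallee_error_configuration")
  }
  simulate_study(scenario, seed = seed)
}
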