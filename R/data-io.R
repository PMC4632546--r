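# Delimited-text readers and writers for the study tables, plus a JSON
# sidecar for the standardization spec so prediction axes can be
# back-transformed without the original data.

FEMALE_COLS <- readr::cols(
  female_id = readr::col_character(),
  population_id = readr::col_character(),
  date = readr::col_character(),
  year = readr::col_integer(),
  y = readr::col_integer(),
  n = readr::col_integer(),
  den = readr::col_double(),
  vel = readr::col_double(),
  dep = readr::col_double(),
  sub = readr::col_double(),
  loc = readr::col_double(),
  shell = readr::col_double(),
  usable = readr::col_logical()
)

POPULATION_COLS <- readr::cols(
  population_id = readr::col_character(),
  year = readr::col_integer(),
  p_den = readr::col_double(),
  cat = readr::col_double()
)

#' Read and write study tables
#'
#' Per-female records are one row per gravid female
#' (`female_id, population_id, date, year, y, n, den, vel, dep, sub, loc,
#' shell, usable`); per-population records are one row per population x year
#' replicate (`population_id, year, p_den, cat`). Values round-trip exactly
#' for counts and to full double precision for reals.
#'
#' @param path File path.
#' @param females,populations Data frames as produced by the simulator or
#'   assembled from field data.
#' @return Readers return a tibble; writers return the input invisibly.
#' @export
read_females_csv <- function(path) {
  readr::read_csv(path, col_types = FEMALE_COLS)
}

#' @rdname read_females_csv
#' @export
read_populations_csv <- function(path) {
  readr::read_csv(path, col_types = POPULATION_COLS)
}

#' @rdname read_females_csv
#' @export
write_females_csv <- function(females, path) {
  readr::write_csv(tibble::as_tibble(females), path)
  invisible(females)
}

#' @rdname read_females_csv
#' @export
write_populations_csv <- function(populations, path) {
  readr::write_csv(tibble::as_tibble(populations), path)
  invisible(populations)
}

#' Standardization-spec sidecar
#'
#' Stores the per-covariate means and standard deviations used for z-scoring
#' as JSON next to the data, so fitted coefficients and prediction grids can
#' be mapped back to natural units later.
#'
#' @param spec A standardization spec tibble (`design$spec`) or a
#'   `fert_design`.
#' @param path JSON file path.
#' @return `write_standardization_json()` returns the spec invisibly;
#'   `read_standardization_json()` returns the spec tibble.
#' @export
write_standardization_json <- function(spec, path) {
  if (inherits(spec, "fert_design")) spec <- spec$spec
  jsonlite::write_json(spec, path, digits = NA)
  invisible(spec)
}

#' @rdname write_standardization_json
#' @export
read_standardization_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
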