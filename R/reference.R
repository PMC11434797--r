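# Reference fixtures: the six granule batches, the press setpoint ranges
# used for each batch, and the reference fitted parameter set.

#' The six reference granule batches
#'
#' Granule batches produced at roll pressures of 30, 60 and 90 bar and roll
#' gaps of 2 and 3 mm, each described by its ribbon relative density and
#' bimodal Weibull granule size distribution. Mode means and the mean
#' granule size are recomputed from the Weibull parameters; the
#' `*_printed_um` columns carry the originally tabulated means as metadata
#' only (two low-pressure rows are inconsistent with the defining
#' gamma-function mean and are never used in computation).
#'
#' @return A tibble with one row per batch: `batch`, `roll_pressure_bar`,
#'   `roll_gap_mm`, `alpha`, `lambda1`, `k1`, `lambda2`, `k2`,
#'   `ribbon_density`, printed-mean metadata, and recomputed `mu1`, `mu2`,
#'   `mu_gsd` (um).
#' @export
#'
#' @examples
#' granule_batches()
granule_batches <- function() {
  path <- system.file("extdata", "granule_batches.csv", package = "tabletrom",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(lambda1 = "lambda1_um", lambda2 = "lambda2_um") |>
    add_gsd_means()
}

#' Press setpoint ranges per batch
#'
#' Dosing-position and main-compression-thickness operating windows chosen
#' for each granule batch so that tablets span a broad range of relative
#' densities without exceeding the press force limit.
#'
#' @return A tibble with columns `batch`, `t_fill_min`, `t_fill_max`,
#'   `t_in_die_min`, `t_in_die_max` (mm).
#' @export
press_setpoint_ranges <- function() {
  tibble::tribble(
    ~batch, ~t_fill_min, ~t_fill_max, ~t_in_die_min, ~t_in_die_max,
    1L, 7.0, 8.5, 2.5, 3.0,
    2L, 7.0, 8.0, 2.5, 3.2,
    3L, 7.5, 9.0, 2.5, 3.0,
    4L, 7.0, 8.0, 2.5, 3.2,
    5L, 8.0, 9.0, 3.5, 4.0,
    6L, 7.0, 7.3, 3.0, 3.3
  )
}

#' Reference fitted parameter set
#'
#' The complete fitted parameter set for the four coupled reduced-order
#' models (packing-fraction weight model, Kawakita force, elastic recovery,
#' Leuenberger strength), shipped as a versioned structured configuration
#' and read back without loss.
#'
#' @param path Optional path to an alternative parameter file (YAML with the
#'   same schema).
#'
#' @return A nested list with elements `version`, `formulation`, `tool`,
#'   `weight`, `force`, `recovery`, `strength`.
#' @export
#'
#' @examples
#' p <- reference_parameters()
#' p$force$a_surface$p4
reference_parameters <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_parameters.yaml",
                                package = "tabletrom", mustWork = TRUE)
  yaml::read_yaml(path)
}
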