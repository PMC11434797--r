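# Synthetic tableting-campaign generator: emulates a steady-state campaign
# (per-tablet weight, punch force, thickness and hardness records) from the
# coupled model chain, for end-to-end and parameter-recovery studies.

#' Tableting conditions across the press setpoint windows
#'
#' Expands each granule batch into `n_per_batch` tableting conditions, one
#' per target in-die relative density. The main-compression thickness is
#' evenly spaced across the batch's window (thick to thin, so the target
#' density rises); the dosing position is chosen, using the weight model,
#' as the value whose fill weight realises the target density at that
#' thickness, then clipped to the press's dosing operating range. This
#' mirrors model-guided experiment design: a blind pairing of window
#' extremes would demand in-die densities above 1 for the wider dosing
#' windows.
#'
#' @param batches A data frame of granule batches with a `batch` column
#'   (default [granule_batches()]).
#' @param ranges Setpoint windows per batch (default
#'   [press_setpoint_ranges()]).
#' @param n_per_batch Conditions per batch.
#' @param rho_targets Target in-die relative densities, one per condition
#'   (recycled to `n_per_batch`).
#' @param dosing_limits Press operating range for the dosing position, mm.
#' @param params Parameter set supplying the weight model, tool geometry
#'   and true density.
#'
#' @return A tibble of conditions: batch attributes plus `condition`,
#'   `t_fill`, `t_in_die` (mm).
#' @export
#'
#' @examples
#' campaign_conditions() |> nrow() # 24
campaign_conditions <- function(batches = granule_batches(),
                                ranges = press_setpoint_ranges(),
                                n_per_batch = 4,
                                rho_targets = seq(0.74, 0.92,
                                                  length.out = n_per_batch),
                                dosing_limits = c(6, 14),
                                params = reference_parameters()) {
  geom <- tool_geometry(params$tool$D_mm, params$tool$h_mm)
  rho_t <- params$formulation$true_density_gcc
  joined <- dplyr::inner_join(tibble::as_tibble(batches), ranges, by = "batch")
  rho_targets <- rep_len(rho_targets, n_per_batch)
  window_cols <- c("t_fill_min", "t_fill_max", "t_in_die_min", "t_in_die_max")
  phi <- batch_packing_fraction(joined, params$weight)
  purrr::map(seq_len(nrow(joined)), function(i) {
    row <- joined[i, ]
    t_in_die <- seq(row$t_in_die_max, row$t_in_die_min,
                    length.out = n_per_batch)
    w_needed <- rho_targets * rho_t * volume_compact(geom, t_in_die)
    v_fill <- w_needed / (phi[i] * rho_t * row$ribbon_density)
    t_fill <- (v_fill - volume_cap(geom) / 2) / (pi * geom$D^2 / 4)
    t_fill <- pmin(pmax(t_fill, dosing_limits[1]), dosing_limits[2])
    dplyr::bind_cols(
      row[rep(1, n_per_batch), setdiff(names(row), window_cols)],
      tibble::tibble(
        condition = seq_len(n_per_batch),
        t_fill = t_fill,
        t_in_die = t_in_die
      )
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(condition_id = dplyr::row_number(), .before = 1)
}

#' Simulate a tableting campaign
#'
#' Generates per-tablet records for each condition: weights drawn from a
#' normal distribution with the model-chain mean and relative standard
#' deviation `weight_rsd`; downstream attributes computed tablet-by-tablet
#' through the coupled chain (force, elastic recovery, out-of-die density,
#' tensile strength) with independent multiplicative observation noise
#' `obs_rsd`; thickness and hardness records back-computed from the noisy
#' density and strength so the table mimics raw tablet-tester measurements.
#' Conditions whose noise-free chain violates a model precondition are
#' flagged and skipped with a message.
#'
#' @param conditions Conditions tibble from [campaign_conditions()].
#' @param params Generating parameter set (default
#'   [reference_parameters()]).
#' @param tablets_per_condition Tablets per condition.
#' @param weight_rsd Relative standard deviation of tablet weight.
#' @param obs_rsd Relative observation noise applied to force, density and
#'   strength records.
#' @param seed Integer seed; the campaign is reproducible bit-for-bit.
#'
#' @return A tibble with columns `condition_id`, `batch`, `t_fill_mm`,
#'   `t_in_die_mm`, `tablet`, `W_mg`, `F_punch_kN`, `H_tablet_mm`,
#'   `hardness_N`, carrying the generating seed and noise levels as
#'   attributes (`provenance`).
#' @export
#'
#' @examples
#' camp <- simulate_campaign(campaign_conditions(), tablets_per_condition = 5,
#'                           seed = 1)
simulate_campaign <- function(conditions, params = reference_parameters(),
                              tablets_per_condition = 100,
                              weight_rsd = 0.016, obs_rsd = 0.02, seed = 1) {
  geom <- tool_geometry(params$tool$D_mm, params$tool$h_mm)
  rho_t <- params$formulation$true_density_gcc
  f_rom <- reference_rom("force", params, geom)
  r_rom <- reference_rom("recovery", params, geom)
  s_rom <- reference_rom("strength", params, geom)

  mean_chain <- predict_tablet_cqas(conditions, params, geom)
  sv_f <- surface_values(f_rom, mean_chain)
  sv_r <- surface_values(r_rom, mean_chain)
  sv_s <- surface_values(s_rom, mean_chain)

  one_condition <- function(i) {
    row <- mean_chain[i, ]
    n <- tablets_per_condition
    W <- stats::rnorm(n, row$W_mg, weight_rsd * row$W_mg)
    rho_id <- relative_density(W, volume_compact(geom, row$t_in_die), rho_t)
    # feasibility at the drawn weights
    if (any(rho_id <= sv_f$rho_c[i]) || any(rho_id >= 1) ||
        any(rho_id * (sv_f$a[i] - 1) + sv_f$rho_c[i] <= 0)) {
      rlang::inform(sprintf("Condition %d infeasible at drawn weights; skipped.",
                            row$condition_id))
      return(NULL)
    }
    F_punch <- kawakita_force(rho_id, sv_f$a[i], f_rom$constant,
                              sv_f$rho_c[i], geom) *
      (1 + stats::rnorm(n, 0, obs_rsd))
    eps <- elastic_recovery(rho_id, sv_r$eps0[i], sv_r$rho_c_eps[i],
                            r_rom$constant)
    rho_tab <- out_of_die_density(rho_id, eps) *
      (1 + stats::rnorm(n, 0, obs_rsd))
    t_tab <- thickness_from_density(W, rho_tab, geom, rho_t)
    H_tab <- t_tab + 2 * geom$h
    sigma <- leuenberger_strength(pmax(rho_tab, sv_s$rho_c_sigma[i]),
                                  sv_s$sigma0[i], sv_s$rho_c_sigma[i]) *
      (1 + stats::rnorm(n, 0, obs_rsd))
    hard <- hardness_from_strength(pmax(sigma, 0), geom, H_tab)
    tibble::tibble(
      condition_id = row$condition_id, batch = row$batch,
      t_fill_mm = row$t_fill, t_in_die_mm = row$t_in_die,
      tablet = seq_len(n), W_mg = W, F_punch_kN = F_punch,
      H_tablet_mm = H_tab, hardness_N = hard
    )
  }

  campaign <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(mean_chain)), one_condition) |>
      purrr::compact() |>
      dplyr::bind_rows()
  })
  attr(campaign, "provenance") <- list(
    seed = seed, weight_rsd = weight_rsd, obs_rsd = obs_rsd,
    tablets_per_condition = tablets_per_condition
  )
  campaign
}

#' Condition-level campaign summaries for model fitting
#'
#' Collapses per-tablet records to condition means and derives the
#' fitting observables: in-die relative density from the mean weight,
#' out-of-die relative density from mean weight and thickness, and tensile
#' strength from mean hardness and thickness via the Pitt relation. The
#' result is joined with the batch attributes so it is directly usable by
#' [fit_rom()].
#'
#' @param campaign Per-tablet records from [simulate_campaign()] or
#'   [read_campaign()].
#' @param batches Batch attribute table (default [granule_batches()]).
#' @param params Parameter set supplying tool geometry and true density.
#'
#' @return A tibble with one row per condition: batch attributes,
#'   setpoints, `n`, mean `W_mg`, `F_punch_kN`, `H_tablet_mm`,
#'   `hardness_N`, and derived `rho_in_die`, `rho_tablet`, `sigma_t_mpa`.
#' @export
summarize_campaign <- function(campaign, batches = granule_batches(),
                               params = reference_parameters()) {
  geom <- tool_geometry(params$tool$D_mm, params$tool$h_mm)
  rho_t <- params$formulation$true_density_gcc
  campaign |>
    dplyr::group_by(.data$condition_id, .data$batch,
                    .data$t_fill_mm, .data$t_in_die_mm) |>
    dplyr::summarise(
      n = dplyr::n(),
      W_mg = mean(.data$W_mg),
      F_punch_kN = mean(.data$F_punch_kN),
      H_tablet_mm = mean(.data$H_tablet_mm),
      hardness_N = mean(.data$hardness_N),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      t_fill = .data$t_fill_mm, t_in_die = .data$t_in_die_mm,
      rho_in_die = relative_density(
        .data$W_mg, volume_compact(geom, .data$t_in_die_mm), rho_t),
      rho_tablet = relative_density(
        .data$W_mg, volume_compact(geom, .data$H_tablet_mm - 2 * geom$h),
        rho_t),
      sigma_t_mpa = tensile_strength_pitt(.data$hardness_N, geom,
                                          .data$H_tablet_mm)
    ) |>
    dplyr::inner_join(batches, by = "batch")
}
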