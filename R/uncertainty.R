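# Monte Carlo propagation of tablet-weight variability through the coupled
# model chain to force, out-of-die density and tensile strength.

#' Tablet-weight distribution specification
#'
#' The measured tablet weight is modelled as normal with a mean given by the
#' packing-fraction weight model and a fixed relative standard deviation
#' (default 1.6%).
#'
#' @param mean_W Mean tablet weight, mg.
#' @param rsd Relative standard deviation (sd/mean), >= 0.
#'
#' @return An object of class `weight_distribution` with elements `mean`
#'   and `sd`; supports `quantile()`.
#' @export
#'
#' @examples
#' weight_distribution(300, rsd = 0.016)
weight_distribution <- function(mean_W, rsd = 0.016) {
  check_positive(mean_W, "mean_W")
  if (rsd < 0) stop_domain("`rsd` must be non-negative.")
  structure(list(mean = mean_W, sd = rsd * mean_W),
            class = "weight_distribution")
}

#' @export
print.weight_distribution <- function(x, ...) {
  cat(sprintf("<weight_distribution> Normal(mean = %g mg, sd = %g mg)\n",
              x$mean, x$sd))
  invisible(x)
}

#' @export
quantile.weight_distribution <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  if (x$sd == 0) return(setNames(rep(x$mean, length(probs)), probs))
  setNames(stats::qnorm(probs, x$mean, x$sd), probs)
}

#' Propagate weight variability to downstream quality attributes
#'
#' For each tableting condition, draws `n_samples` tablet weights from the
#' modelled normal distribution, holds the in-die thickness fixed so that
#' weight variation maps to in-die density variation, and pushes each draw
#' through the coupled chain: compaction force, elastic recovery,
#' out-of-die density, tensile strength. Draws violating a model
#' precondition (non-positive weight, density at or beyond a critical
#' bound) are rejected and counted.
#'
#' @param conditions Conditions tibble (batch attributes plus `t_fill`,
#'   `t_in_die`), e.g. from [campaign_conditions()].
#' @param params Parameter set from [reference_parameters()].
#' @param rsd Relative standard deviation of tablet weight.
#' @param n_samples Monte Carlo sample count per condition.
#' @param seed Integer seed; summaries are bitwise reproducible.
#'
#' @return A tibble with one row per condition: `W_mean`, `W_sd`,
#'   `F_mean`, `F_sd` (kN), `rho_tablet_mean`, `rho_tablet_sd`,
#'   `sigma_mean`, `sigma_sd` (MPa), `n_samples`, `rejected_fraction`.
#' @export
#'
#' @examples
#' cond <- campaign_conditions()[1, ]
#' propagate_uncertainty(cond, n_samples = 1000, seed = 42)
propagate_uncertainty <- function(conditions, params = reference_parameters(),
                                  rsd = 0.016, n_samples = 10000, seed = 1) {
  if (n_samples < 1) stop_domain("`n_samples` must be at least 1.")
  geom <- tool_geometry(params$tool$D_mm, params$tool$h_mm)
  rho_t <- params$formulation$true_density_gcc
  chain <- predict_tablet_cqas(conditions, params, geom)
  sv_f <- surface_values(reference_rom("force", params, geom), chain)
  sv_r <- surface_values(reference_rom("recovery", params, geom), chain)
  sv_s <- surface_values(reference_rom("strength", params, geom), chain)

  one_condition <- function(i) {
    row <- chain[i, ]
    wd <- weight_distribution(row$W_mg, rsd)
    W <- if (wd$sd == 0) rep(wd$mean, n_samples) else {
      stats::rnorm(n_samples, wd$mean, wd$sd)
    }
    rho_id <- relative_density(pmax(W, .Machine$double.eps),
                               volume_compact(geom, row$t_in_die), rho_t)
    ok <- W > 0 &
      rho_id > sv_f$rho_c[i] & rho_id < 1 &
      rho_id * (sv_f$a[i] - 1) + sv_f$rho_c[i] > 0 &
      rho_id >= sv_r$rho_c_eps[i]
    Wk <- W[ok]
    rho_k <- rho_id[ok]
    F_punch <- kawakita_force(rho_k, sv_f$a[i], params$force$b_per_gpa,
                              sv_f$rho_c[i], geom)
    eps <- elastic_recovery(rho_k, sv_r$eps0[i], sv_r$rho_c_eps[i],
                            params$recovery$n_exp)
    rho_tab <- out_of_die_density(rho_k, eps)
    coherent <- rho_tab >= sv_s$rho_c_sigma[i]
    sigma <- leuenberger_strength(pmax(rho_tab, sv_s$rho_c_sigma[i]),
                                  sv_s$sigma0[i], sv_s$rho_c_sigma[i])
    keep <- ok
    keep[which(ok)[!coherent]] <- FALSE
    tibble::tibble(
      condition_id = row$condition_id %||% i, batch = row$batch,
      t_fill = row$t_fill, t_in_die = row$t_in_die,
      W_mean = mean(Wk[coherent]), W_sd = sd(Wk[coherent]),
      F_mean = mean(F_punch[coherent]), F_sd = sd(F_punch[coherent]),
      rho_tablet_mean = mean(rho_tab[coherent]),
      rho_tablet_sd = sd(rho_tab[coherent]),
      sigma_mean = mean(sigma[coherent]), sigma_sd = sd(sigma[coherent]),
      n_samples = n_samples,
      rejected_fraction = 1 - sum(keep) / n_samples
    )
  }

  withr::with_seed(seed, {
    purrr::map(seq_len(nrow(chain)), one_condition) |> dplyr::bind_rows()
  })
}
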