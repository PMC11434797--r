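# Coupled reduced-order models: the base tableting ROMs with their
# parameters replaced by rational surfaces of normalized upstream
# attributes (ribbon relative density, mean granule size, packing fraction).

surface_from_config <- function(cfg) {
  rational_surface(
    cfg$variant,
    p1 = cfg$p1 %||% 0, p2 = cfg$p2 %||% 0, p3 = cfg$p3 %||% 0,
    p4 = cfg$p4 %||% 0,
    q1 = cfg$q1 %||% 0, q2 = cfg$q2 %||% 0, q3 = cfg$q3 %||% 0
  )
}

#' Coupled reduced-order model
#'
#' Bundles a base tableting ROM with the rational surfaces that couple its
#' parameters to upstream attributes. For `force` and `recovery` the two
#' covariates are the normalized ribbon relative density
#' \eqn{X = ((\rho_{ribbon} - \rho_{c,rib})/(1 - \rho_{ribbon}))^{r_X}} and
#' normalized mean granule size \eqn{Y = (\mu_{GSD}/(D/6 - \mu_{GSD}))^{r_Y}}
#' (upper bound: one sixth of the die diameter, the largest mean granule
#' size compatible with proper die filling). For `strength` the second
#' covariate is the normalized packing fraction
#' \eqn{Z = ((\phi - \phi_{min})/(\phi_{max} - \phi))^{r_Z}}. The `weight`
#' model is the single constrained packing surface and has no free pair.
#'
#' @param cqa One of `"weight"`, `"force"`, `"recovery"`, `"strength"`.
#' @param surface1,surface2 [rational_surface()] objects for the two coupled
#'   parameters (`a`/`rho_c`, `eps0`/`rho_c_eps`, or `sigma0`/`rho_c_sigma`).
#'   Ignored for `"weight"`.
#' @param rX,rY Shared normalization exponents (for `"strength"`, `rY` is
#'   the packing-fraction exponent `rZ`).
#' @param constant Scalar constant fitted alongside the surfaces: the
#'   Kawakita pressure parameter `b` (1/GPa) for `"force"`, the recovery
#'   exponent `n` for `"recovery"`; `NULL` otherwise.
#' @param weight Packing-surface coefficients, a list with `p4`, `q1`, `q2`
#'   and (for the strength covariate) `phi_min`, `phi_max`.
#' @param rho_c_rib Critical ribbon relative density (lower normalization
#'   bound for the ribbon density), shared by all coupled models.
#' @param geom A [tool_geometry()].
#' @param rho_t True density of the formulation, g/cc.
#'
#' @return An object of class `coupled_rom`.
#' @export
#'
#' @examples
#' rom <- reference_rom("force")
#' surface_values(rom, granule_batches())
coupled_rom <- function(cqa = c("weight", "force", "recovery", "strength"),
                        surface1 = NULL, surface2 = NULL,
                        rX = 1, rY = 1, constant = NULL,
                        weight = NULL, rho_c_rib = 0.566,
                        geom = tool_geometry(), rho_t = 1.558) {
  cqa <- match.arg(cqa)
  if (cqa != "weight") {
    surface1 <- as_rational_surface(surface1)
    surface2 <- as_rational_surface(surface2)
  }
  if (cqa %in% c("force", "recovery") && is.null(constant)) {
    stop_domain(sprintf("`constant` (%s) is required for the %s model.",
                        if (cqa == "force") "b" else "n", cqa))
  }
  if (cqa %in% c("weight", "strength") && is.null(weight)) {
    stop_domain("Packing-surface coefficients `weight` are required.")
  }
  structure(
    list(cqa = cqa, surface1 = surface1, surface2 = surface2,
         rX = rX, rY = rY, constant = constant, weight = weight,
         rho_c_rib = rho_c_rib, geom = as_tool_geometry(geom), rho_t = rho_t),
    class = "coupled_rom"
  )
}

#' @export
print.coupled_rom <- function(x, ...) {
  cat(sprintf("<coupled_rom> %s\n", x$cqa))
  if (!is.null(x$surface1)) {
    cat(sprintf("  surfaces: variants (%d, %d); exponents (%.3g, %.3g)\n",
                x$surface1$variant, x$surface2$variant, x$rX, x$rY))
  }
  if (!is.null(x$constant)) cat(sprintf("  constant: %g\n", x$constant))
  invisible(x)
}

#' Reference coupled model for one quality attribute
#'
#' Builds a [coupled_rom()] from the reference fitted parameter set.
#'
#' @param cqa One of `"weight"`, `"force"`, `"recovery"`, `"strength"`.
#' @param params A parameter set from [reference_parameters()].
#' @param geom A [tool_geometry()]; defaults to the tool recorded in
#'   `params`.
#'
#' @return A `coupled_rom`.
#' @export
reference_rom <- function(cqa, params = reference_parameters(), geom = NULL) {
  geom <- geom %||% tool_geometry(params$tool$D_mm, params$tool$h_mm)
  rho_t <- params$formulation$true_density_gcc
  rho_c_rib <- params$formulation$rho_c_rib
  switch(cqa,
    weight = coupled_rom("weight", weight = params$weight,
                         rho_c_rib = rho_c_rib, geom = geom, rho_t = rho_t),
    force = coupled_rom(
      "force",
      surface1 = surface_from_config(params$force$a_surface),
      surface2 = surface_from_config(params$force$rho_c_surface),
      rX = params$force$rX, rY = params$force$rY,
      constant = params$force$b_per_gpa,
      rho_c_rib = rho_c_rib, geom = geom, rho_t = rho_t
    ),
    recovery = coupled_rom(
      "recovery",
      surface1 = surface_from_config(params$recovery$eps0_surface),
      surface2 = surface_from_config(params$recovery$rho_c_eps_surface),
      rX = params$recovery$rX, rY = params$recovery$rY,
      constant = params$recovery$n_exp,
      rho_c_rib = rho_c_rib, geom = geom, rho_t = rho_t
    ),
    strength = coupled_rom(
      "strength",
      surface1 = surface_from_config(params$strength$sigma0_surface),
      surface2 = surface_from_config(params$strength$rho_c_sigma_surface),
      rX = params$strength$rX, rY = params$strength$rZ,
      weight = params$weight,
      rho_c_rib = rho_c_rib, geom = geom, rho_t = rho_t
    ),
    stop_domain("Unknown CQA.")
  )
}

# Packing fraction of each batch from the weight-model coefficients.
batch_packing_fraction <- function(batches, weight) {
  batches <- add_packing_covariates(batches)
  packing_fraction(batches$X_pack, batches$Y_pack,
                   p4 = weight$p4, q1 = weight$q1, q2 = weight$q2)
}

#' Normalized coupling covariates for granule batches
#'
#' Computes the covariates a coupled model sees for each batch: `X`
#' (normalized ribbon relative density) and, depending on the model, `Y`
#' (normalized mean granule size) or `Z` (normalized packing fraction).
#'
#' @param rom A [coupled_rom()].
#' @param batches A data frame of granule batches (see [granule_batches()]).
#'
#' @return The batches tibble with covariate columns appended (`X` and `Y`;
#'   for `"weight"`, `X_pack` and `Y_pack`).
#' @export
rom_covariates <- function(rom, batches) {
  stopifnot(inherits(rom, "coupled_rom"))
  batches <- add_gsd_means(tibble::as_tibble(batches))
  if (rom$cqa == "weight") {
    return(add_packing_covariates(batches))
  }
  X <- normalize_variable(batches$ribbon_density, rom$rho_c_rib, 1, rom$rX)
  if (rom$cqa == "strength") {
    phi <- batch_packing_fraction(batches, rom$weight)
    Y <- normalize_variable(phi, rom$weight$phi_min, rom$weight$phi_max, rom$rY)
    return(dplyr::mutate(batches, phi = phi, X = X, Y = Y))
  }
  ub_um <- rom$geom$D * 1000 / 6
  Y <- normalize_variable(batches$mu_gsd, 0, ub_um, rom$rY)
  dplyr::mutate(batches, X = X, Y = Y)
}

#' Coupled parameter values at each batch
#'
#' Evaluates the model's two rational surfaces at each batch's covariates,
#' returning the effective base-ROM parameters per batch (e.g. the Kawakita
#' `a` and `rho_c` for the force model).
#'
#' @inheritParams rom_covariates
#'
#' @return The batches tibble with two columns appended, named after the
#'   coupled parameters (`a`/`rho_c`, `eps0`/`rho_c_eps`, or
#'   `sigma0`/`rho_c_sigma`).
#' @export
surface_values <- function(rom, batches) {
  stopifnot(inherits(rom, "coupled_rom"))
  if (rom$cqa == "weight") {
    batches <- add_packing_covariates(tibble::as_tibble(batches))
    return(dplyr::mutate(
      batches,
      phi = packing_fraction(.data$X_pack, .data$Y_pack, rom$weight$p4,
                             rom$weight$q1, rom$weight$q2)
    ))
  }
  cov <- rom_covariates(rom, batches)
  v1 <- eval_surface(rom$surface1, cov$X, cov$Y)
  v2 <- eval_surface(rom$surface2, cov$X, cov$Y)
  nms <- switch(rom$cqa,
    force = c("a", "rho_c"),
    recovery = c("eps0", "rho_c_eps"),
    strength = c("sigma0", "rho_c_sigma")
  )
  cov[[nms[1]]] <- v1
  cov[[nms[2]]] <- v2
  cov
}

#' Evaluate a coupled model
#'
#' Computes the model's quality attribute for granule batches at given
#' tableting states: tablet weight needs the dosing position `t_fill`;
#' compaction force and elastic recovery need the in-die relative density;
#' tensile strength needs the out-of-die relative density.
#'
#' @param rom A [coupled_rom()].
#' @param batches Data frame of granule batches, one row per evaluation.
#' @param t_fill Dosing position, mm (weight model).
#' @param rho_in_die In-die relative density (force and recovery models).
#' @param rho_tablet Out-of-die relative density (strength model).
#'
#' @return Numeric vector: weight in mg, force in kN, recovery strain, or
#'   tensile strength in MPa.
#' @export
#'
#' @examples
#' b <- granule_batches()
#' evaluate_coupled(reference_rom("force"), b, rho_in_die = 0.85)
evaluate_coupled <- function(rom, batches, t_fill = NULL,
                             rho_in_die = NULL, rho_tablet = NULL) {
  stopifnot(inherits(rom, "coupled_rom"))
  vals <- surface_values(rom, batches)
  switch(rom$cqa,
    weight = {
      if (is.null(t_fill)) stop_domain("`t_fill` is required for the weight model.")
      vals$phi * rom$rho_t * vals$ribbon_density * volume_fill(rom$geom, t_fill)
    },
    force = {
      if (is.null(rho_in_die)) stop_domain("`rho_in_die` is required for the force model.")
      kawakita_force(rho_in_die, a = vals$a, b = rom$constant,
                     rho_c = vals$rho_c, geom = rom$geom)
    },
    recovery = {
      if (is.null(rho_in_die)) stop_domain("`rho_in_die` is required for the recovery model.")
      elastic_recovery(rho_in_die, eps0 = vals$eps0,
                       rho_c_eps = vals$rho_c_eps, n = rom$constant)
    },
    strength = {
      if (is.null(rho_tablet)) stop_domain("`rho_tablet` is required for the strength model.")
      leuenberger_strength(rho_tablet, sigma0 = vals$sigma0,
                           rho_c_sigma = vals$rho_c_sigma)
    }
  )
}

#' Predict all tablet quality attributes along the coupled chain
#'
#' Runs the full deterministic model chain for each tableting condition:
#' packing fraction and tablet weight from the dosing position, in-die
#' relative density from the main-compression thickness, compaction force,
#' elastic recovery, out-of-die density, and tensile strength.
#'
#' @param conditions A data frame with one row per tableting condition,
#'   containing the batch attributes (`ribbon_density`, `alpha`, `lambda1`,
#'   `k1`, `lambda2`, `k2`) and the press setpoints `t_fill` and `t_in_die`
#'   (mm).
#' @param params Parameter set from [reference_parameters()].
#' @param geom Optional [tool_geometry()] overriding the one in `params`.
#'
#' @return The conditions tibble with columns `phi`, `W_mg`, `rho_in_die`,
#'   `F_punch_kN`, `eps_rho`, `rho_tablet`, `sigma_t_mpa` appended.
#' @export
#'
#' @examples
#' granule_batches() |>
#'   dplyr::mutate(t_fill = 8, t_in_die = 3) |>
#'   predict_tablet_cqas()
predict_tablet_cqas <- function(conditions, params = reference_parameters(),
                                geom = NULL) {
  geom <- geom %||% tool_geometry(params$tool$D_mm, params$tool$h_mm)
  rho_t <- params$formulation$true_density_gcc
  conditions <- add_gsd_means(tibble::as_tibble(conditions))

  w_rom <- reference_rom("weight", params, geom)
  f_rom <- reference_rom("force", params, geom)
  r_rom <- reference_rom("recovery", params, geom)
  s_rom <- reference_rom("strength", params, geom)

  phi <- batch_packing_fraction(conditions, params$weight)
  W <- phi * rho_t * conditions$ribbon_density *
    volume_fill(geom, conditions$t_fill)
  rho_in_die <- relative_density(W, volume_compact(geom, conditions$t_in_die),
                                 rho_t)
  F_punch <- evaluate_coupled(f_rom, conditions, rho_in_die = rho_in_die)
  eps <- evaluate_coupled(r_rom, conditions, rho_in_die = rho_in_die)
  rho_tab <- out_of_die_density(rho_in_die, eps)
  sigma <- evaluate_coupled(s_rom, conditions, rho_tablet = rho_tab)

  dplyr::mutate(conditions, phi = phi, W_mg = W, rho_in_die = rho_in_die,
                F_punch_kN = F_punch, eps_rho = eps, rho_tablet = rho_tab,
                sigma_t_mpa = sigma)
}
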