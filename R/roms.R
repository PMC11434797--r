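# Tableting reduced-order models: Kawakita-type compaction force, elastic
# recovery, out-of-die density, Leuenberger tensile strength, the
# packing-fraction weight model, and the Brouwers bimodal-sphere reference.

#' Kawakita-type compaction force
#'
#' Main-compression punch force as a function of the in-die relative density,
#' modified to depend on the critical (jamming) density `rho_c` at which
#' particle-level deformation begins:
#' \deqn{F = \frac{\pi D^2 (\rho - \rho_c)}{4 b (\rho(a - 1) + \rho_c)}.}
#' Feasibility requires \eqn{\rho > \rho_c} and \eqn{\rho(a-1) + \rho_c > 0};
#' violations signal an infeasible state rather than returning a negative
#' force.
#'
#' @param rho_in_die In-die relative density (vectorised).
#' @param a Kawakita total compressibility, in (0, 1).
#' @param b Kawakita pressure parameter, 1/GPa (as conventionally reported;
#'   converted internally so the force emerges in kN).
#' @param rho_c Critical in-die relative density at jamming.
#' @param geom A [tool_geometry()].
#'
#' @return Punch force, kN.
#' @export
#'
#' @examples
#' kawakita_force(0.85, a = 0.765, b = 61.39, rho_c = 0.33, tool_geometry())
kawakita_force <- function(rho_in_die, a, b, rho_c, geom = tool_geometry()) {
  geom <- as_tool_geometry(geom)
  check_positive(b, "b")
  if (any(rho_in_die < rho_c)) {
    stop_domain("Infeasible state: rho_in_die below the jamming density rho_c.")
  }
  den <- rho_in_die * (a - 1) + rho_c
  if (any(den <= 0 & rho_in_die > rho_c)) {
    stop_domain("Infeasible state: rho_in_die * (a - 1) + rho_c must be positive.")
  }
  b_mpa <- b / 1000 # 1/GPa -> 1/MPa
  force_n <- pi * geom$D^2 * (rho_in_die - rho_c) / (4 * b_mpa * den)
  force_n / 1000 # N -> kN (D in mm, b in 1/MPa => N)
}

#' Elastic recovery on unloading
#'
#' Fractional in-die elastic recovery,
#' \deqn{\epsilon_\rho = \epsilon_0 \left(\frac{\rho - \rho_{c,\epsilon}}{1 - \rho_{c,\epsilon}}\right)^n,}
#' where `eps0` is the recovery at zero porosity, `rho_c_eps` the onset
#' density, and `n` a nonlinearity exponent. Below the onset the recovery is
#' zero by convention (a message is emitted once per call).
#'
#' @param rho_in_die In-die relative density (vectorised).
#' @param eps0 Recovery at full compaction, in (0, 1).
#' @param rho_c_eps Onset density of elastic recovery, in (0, 1).
#' @param n Nonlinearity exponent, > 0.
#'
#' @return Recovery strain, dimensionless.
#' @export
elastic_recovery <- function(rho_in_die, eps0, rho_c_eps, n) {
  check_positive(n, "n")
  below <- rho_in_die < rho_c_eps
  if (any(below)) {
    rlang::inform("Relative density below recovery onset: returning zero recovery.")
  }
  out <- numeric(length(rho_in_die))
  out[!below] <-
    eps0 * ((rho_in_die[!below] - rho_c_eps) / (1 - rho_c_eps))^n
  out
}

#' Out-of-die tablet relative density
#'
#' \deqn{\rho_{tablet} = \rho_{in-die} (1 - \epsilon_\rho).}
#'
#' @param rho_in_die In-die relative density.
#' @param eps_rho Elastic recovery strain, in \[0, 1).
#'
#' @return Out-of-die relative density.
#' @export
out_of_die_density <- function(rho_in_die, eps_rho) {
  if (any(eps_rho < 0 | eps_rho >= 1)) {
    stop_domain("`eps_rho` must lie in [0, 1).")
  }
  rho_in_die * (1 - eps_rho)
}

#' Leuenberger tensile strength
#'
#' Tensile strength as a function of out-of-die relative density,
#' \deqn{\sigma_t = \sigma_0 \left[1 - \frac{1 - \rho}{1 - \rho_{c,\sigma}}
#'   e^{\rho - \rho_{c,\sigma}}\right],}
#' rising from zero at the smallest coherent-tablet density `rho_c_sigma` to
#' the zero-porosity maximum `sigma0` at \eqn{\rho = 1}.
#'
#' @param rho_tablet Out-of-die relative density (vectorised).
#' @param sigma0 Maximum tensile strength at zero porosity, MPa.
#' @param rho_c_sigma Smallest density forming a coherent tablet, in (0, 1).
#'
#' @return Tensile strength, MPa.
#' @export
leuenberger_strength <- function(rho_tablet, sigma0, rho_c_sigma) {
  check_positive(sigma0, "sigma0")
  if (any(rho_tablet < rho_c_sigma)) {
    stop_domain("No coherent tablet: rho_tablet below rho_c_sigma.")
  }
  sigma0 * (1 - (1 - rho_tablet) / (1 - rho_c_sigma) *
              exp(rho_tablet - rho_c_sigma))
}

#' Packing fraction of bimodal granules in the die
#'
#' Die-filling packing fraction as a constrained rational surface of the
#' packing covariates (see [packing_covariates()]):
#' \deqn{\phi(X, Y) = p_4 \frac{q_2 X + 1}{q_1 X Y + q_2 X + 1},}
#' with \eqn{p_4} the unimodal packing fraction and \eqn{q_1 < 0} so that
#' \eqn{\phi \ge p_4} over the unit square. `q1` is stored signed; fitted
#' magnitudes are reported as positive numbers elsewhere but enter here with
#' their negative sign.
#'
#' @param X,Y Packing covariates in \[0, 1\] (vectorised, recycled).
#' @param p4 Unimodal packing fraction, in (0, 1).
#' @param q1 Interaction coefficient (negative under the fitted constraint).
#' @param q2 Size-effect coefficient.
#'
#' @return Packing fraction, dimensionless.
#' @export
#'
#' @examples
#' packing_fraction(0.3, 0.7, p4 = 0.367, q1 = -6.08, q2 = 7.33)
packing_fraction <- function(X, Y, p4, q1, q2) {
  if (any(X < 0 | X > 1) || any(Y < 0 | Y > 1)) {
    stop_domain("Packing covariates must lie in [0, 1].")
  }
  if (p4 <= 0 || p4 >= 1) stop_domain("`p4` must lie in (0, 1).")
  den <- q1 * X * Y + q2 * X + 1
  if (any(den <= 0)) stop_singular("Non-positive packing-surface denominator.")
  p4 * (q2 * X + 1) / den
}

#' Tablet weight from the packing-fraction model
#'
#' \deqn{W = \phi(X, Y)\,\rho_t\,\rho_{ribbon}\,V_{fill},} with the packing
#' covariates computed from the batch granule size distribution. The bulk
#' density of the granules is expressed as the packing fraction times the
#' envelope density \eqn{\rho_t \rho_{ribbon}}.
#'
#' @param batch A one-row data frame (or list) with `ribbon_density`,
#'   `alpha`, `lambda1`, `k1`, `lambda2`, `k2`.
#' @param p4,q1,q2 Packing-surface coefficients (see [packing_fraction()]).
#' @param geom A [tool_geometry()].
#' @param t_fill Dosing position, mm.
#' @param rho_t True density, g/cc.
#'
#' @return Tablet weight, mg.
#' @export
tablet_weight <- function(batch, p4, q1, q2, geom = tool_geometry(),
                          t_fill, rho_t = 1.558) {
  gsd <- gsd_from_row(batch)
  xy <- packing_covariates(gsd)
  phi <- packing_fraction(xy[["X"]], xy[["Y"]], p4, q1, q2)
  phi * rho_t * batch$ribbon_density * volume_fill(geom, t_fill)
}

#' Brouwers reference packing fraction for bimodal spheres
#'
#' Analytical packing fraction of a randomly packed bimodal mixture of hard
#' monodisperse spheres, used here as a qualitative reference for the fitted
#' granule packing surface. With `u` the mode size ratio (small over large)
#' and `alpha` the fraction of the small mode:
#' \deqn{\phi = \phi_{rp}\frac{(1-\alpha)(1-u^3) + u^3}
#'   {C(1-\alpha)\alpha(u^3 - 1) + (1-\alpha)(1-u^3) + u^3}.}
#' At `u = 1` or `C = 0` the expression collapses to the unimodal random
#' packing fraction `phi_rp`; for `C > 0` it satisfies `phi >= phi_rp`.
#'
#' @param size_ratio Mode size ratio in (0, 1\].
#' @param alpha Fraction of the small mode, in \[0, 1\].
#' @param phi_rp Random packing fraction of unimodal spheres.
#' @param C Packing-mode constant (e.g. loose vs close random packing).
#'
#' @return Packing fraction, dimensionless.
#' @export
brouwers_packing <- function(size_ratio, alpha, phi_rp = 0.64, C = 0.2) {
  if (any(size_ratio <= 0 | size_ratio > 1)) {
    stop_domain("`size_ratio` must lie in (0, 1].")
  }
  if (any(alpha < 0 | alpha > 1)) stop_domain("`alpha` must lie in [0, 1].")
  u3 <- size_ratio^3
  num <- (1 - alpha) * (1 - u3) + u3
  den <- C * (1 - alpha) * alpha * (u3 - 1) + num
  phi_rp * num / den
}
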