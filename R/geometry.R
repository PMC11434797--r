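# Doubly convex tablet geometry and per-tablet derived quantities.
#
# Unit contract used throughout the package: lengths in mm, volumes in mm^3,
# weights in mg, densities in g/cc (numerically equal to mg/mm^3), diametral
# breaking force (hardness) in N, punch force in kN, stresses in MPa.

#' Punch/die tool geometry
#'
#' Describes a doubly convex compression tool by its diameter and cup depth.
#' The defaults are the D-type tool used throughout the package's worked
#' examples (7.94 mm diameter, 0.3302 mm standard cup).
#'
#' @param D Punch/die diameter, mm.
#' @param h Cup depth, mm. `h = 0` describes a flat-faced tool.
#'
#' @return An object of class `tool_geometry`: a named list with elements
#'   `D` and `h`.
#' @export
#'
#' @examples
#' tool_geometry()
#' tool_geometry(D = 10, h = 0)
tool_geometry <- function(D = 7.94, h = 0.3302) {
  check_positive(D, "D")
  if (!is.finite(h) || h < 0) stop_domain("`h` must be non-negative.")
  if (h >= D / 2) stop_domain("Cup depth `h` must be smaller than D/2.")
  structure(list(D = D, h = h), class = "tool_geometry")
}

#' @export
print.tool_geometry <- function(x, ...) {
  cat(sprintf("<tool_geometry> D = %g mm, h = %g mm\n", x$D, x$h))
  invisible(x)
}

as_tool_geometry <- function(geom) {
  if (inherits(geom, "tool_geometry")) return(geom)
  stop_domain("`geom` must be a `tool_geometry` object.")
}

#' Tablet cap, fill and compact volumes
#'
#' `volume_cap()` returns the combined volume of the two spherical end caps,
#' \eqn{\pi h/6 (3D^2/4 + h^2)}. `volume_fill()` is the die volume at dosing
#' position `t_fill`, which carries half the cap term (the die is open at the
#' top during filling): \eqn{\pi D^2 t/4 + \pi h/12 (3D^2/4 + h^2)}.
#' `volume_compact()` is the enclosed volume at punch separation `t`
#' (pre-compression, in-die, or relaxed tablet band thickness):
#' \eqn{\pi D^2 t/4 + \pi h/6 (3D^2/4 + h^2)}.
#'
#' @param geom A [tool_geometry()].
#' @param t_fill,t Punch separation, mm. Vectorised.
#'
#' @return Volume(s) in mm^3.
#' @export
#'
#' @examples
#' g <- tool_geometry()
#' volume_cap(g)
#' volume_fill(g, t_fill = 8)
#' volume_compact(g, t = 3)
volume_cap <- function(geom) {
  geom <- as_tool_geometry(geom)
  pi * geom$h / 6 * (3 * geom$D^2 / 4 + geom$h^2)
}

#' @rdname volume_cap
#' @export
volume_fill <- function(geom, t_fill) {
  geom <- as_tool_geometry(geom)
  check_positive(t_fill, "t_fill")
  pi * geom$D^2 * t_fill / 4 + volume_cap(geom) / 2
}

#' @rdname volume_cap
#' @export
volume_compact <- function(geom, t) {
  geom <- as_tool_geometry(geom)
  check_positive(t, "t")
  pi * geom$D^2 * t / 4 + volume_cap(geom)
}

#' Relative density of a compact
#'
#' Ratio of apparent to true density, \eqn{\rho = W / (\rho_t V)}. With W in
#' mg, V in mm^3 and the true density in g/cc the units cancel without
#' conversion factors.
#'
#' @param W Tablet weight, mg. Vectorised.
#' @param V Enclosed volume, mm^3 (see [volume_compact()]).
#' @param rho_t True (pycnometric) density of the formulation, g/cc.
#'
#' @return Relative density (solid fraction), dimensionless.
#' @export
#'
#' @examples
#' relative_density(W = 300, V = 250, rho_t = 1.558)
relative_density <- function(W, V, rho_t = 1.558) {
  check_positive(W, "W")
  check_positive(V, "V")
  check_positive(rho_t, "rho_t")
  W / (rho_t * V)
}

#' Filling efficacy
#'
#' Lumped die-filling coefficient \eqn{\eta = W / (\rho_b V_{fill})}: the
#' ratio of the realised fill weight to the weight an ideally filled die
#' would hold at the off-line bulk density.
#'
#' @param W Tablet weight, mg.
#' @param rho_b Bulk density of the granules, g/cc.
#' @param V_fill Fill volume of the die, mm^3 (see [volume_fill()]).
#'
#' @return Dimensionless efficacy; 1 for ideal filling.
#' @export
filling_efficacy <- function(W, rho_b, V_fill) {
  check_positive(W, "W")
  check_positive(rho_b, "rho_b")
  check_positive(V_fill, "V_fill")
  W / (rho_b * V_fill)
}

pitt_denominator <- function(D, H_tablet, t_tablet) {
  2.84 * H_tablet / D - 0.126 * H_tablet / t_tablet +
    3.15 * t_tablet / D + 0.01
}

#' Tensile strength of a doubly convex tablet (Pitt)
#'
#' Converts a diametral breaking force into a tensile strength for doubly
#' convex tablets:
#' \deqn{\sigma_t = \frac{10F/(\pi D^2)}{2.84 H/D - 0.126 H/t + 3.15 t/D + 0.01},}
#' where \eqn{H} is the overall tablet thickness and \eqn{t = H - 2h} the
#' cylindrical band thickness.
#'
#' @param F_hardness Diametral breaking force, N. Vectorised.
#' @param geom A [tool_geometry()].
#' @param H_tablet Overall tablet thickness, mm.
#'
#' @return Tensile strength, MPa.
#' @export
#'
#' @examples
#' tensile_strength_pitt(100, tool_geometry(), H_tablet = 3.6604)
tensile_strength_pitt <- function(F_hardness, geom, H_tablet) {
  geom <- as_tool_geometry(geom)
  if (any(F_hardness < 0)) stop_domain("`F_hardness` must be non-negative.")
  t_tablet <- H_tablet - 2 * geom$h
  check_positive(t_tablet, "t_tablet (= H_tablet - 2h)")
  den <- pitt_denominator(geom$D, H_tablet, t_tablet)
  if (any(den <= 0)) {
    stop_domain("Non-positive Pitt denominator: geometrically invalid tablet.")
  }
  (10 * F_hardness / (pi * geom$D^2)) / den
}

# Inverse of the Pitt relation: breaking force from tensile strength at a
# given overall thickness. Used when emitting synthetic hardness records.
hardness_from_strength <- function(sigma_t, geom, H_tablet) {
  geom <- as_tool_geometry(geom)
  t_tablet <- H_tablet - 2 * geom$h
  den <- pitt_denominator(geom$D, H_tablet, t_tablet)
  sigma_t * den * pi * geom$D^2 / 10
}

# Band thickness (punch separation) whose compact volume holds weight W at
# relative density rho; inverts volume_compact().
thickness_from_density <- function(W, rho, geom, rho_t = 1.558) {
  geom <- as_tool_geometry(geom)
  V <- W / (rho_t * rho)
  (V - volume_cap(geom)) / (pi * geom$D^2 / 4)
}
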