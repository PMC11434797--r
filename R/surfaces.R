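# Normalization mapping, constrained variants of the normalized bivariate
# rational function, limit algebra, and the 25-pair model library.

#' Normalize a process variable onto \[0, Inf)
#'
#' Maps a bounded raw variable `x` in \[lb, ub) onto the half-line via
#' \deqn{X = \left(\frac{x - lb}{ub - x}\right)^r,}
#' so that `X = 0` at the lower bound and `X` diverges at the upper bound.
#' The exponent `r` accommodates nonlinearity in the coupling.
#'
#' @param x Raw values (vectorised).
#' @param lb,ub Lower and upper bounds, same units as `x`; `lb < ub`.
#' @param r Exponent, in (0, 10\].
#'
#' @return Normalized values in \[0, Inf).
#' @export
#'
#' @examples
#' normalize_variable(0.803, lb = 0.566, ub = 1, r = 10)
normalize_variable <- function(x, lb, ub, r = 1) {
  if (!is.finite(lb) || !is.finite(ub) || lb >= ub) {
    stop_domain("Bounds must satisfy lb < ub.")
  }
  if (!is.finite(r) || r <= 0 || r > 10) {
    stop_domain("Exponent `r` must lie in (0, 10].")
  }
  if (any(x < lb)) {
    stop_domain("`x` below the lower bound of its normalization.")
  }
  if (any(x >= ub)) {
    stop_overflow("`x` at or above the upper bound of its normalization.")
  }
  ((x - lb) / (ub - x))^r
}

# variant bookkeeping ----------------------------------------------------

variant_zeroed <- list(
  `1` = character(0),
  `2` = character(0),
  `3` = c("p3", "q3"),
  `4` = c("p3", "q3"),
  `5` = c("p2", "q2"),
  `6` = c("p2", "q2"),
  `7` = c("p2", "p3", "q2", "q3"),
  `8` = c("p2", "p3", "q2", "q3"),
  `9` = c("p1", "p2", "p3", "q1", "q2", "q3")
)

variant_exponents_fixed <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)

#' Constrained variants of the rational surface
#'
#' The model library is built by progressively zeroing coefficients of the
#' full bivariate rational function and/or fixing both exponents at 1. The
#' nine variants range from the full 9-parameter surface (variant 1) down to
#' a constant (variant 9, `f = p4`).
#'
#' @param id Variant number, 1--9.
#'
#' @return A list with elements `id`, `zeroed` (coefficient names fixed at
#'   zero), `exponents_fixed` (logical: both exponents pinned at 1),
#'   `n_free_coeffs` (free numerator/denominator coefficients, excluding
#'   exponents) and `n_parameters` (including exponents where free).
#' @export
#'
#' @examples
#' variant_spec(8)
variant_spec <- function(id) {
  if (length(id) != 1 || !id %in% 1:9) stop_domain("`id` must be one of 1..9.")
  zeroed <- variant_zeroed[[as.character(id)]]
  n_free <- 7L - length(zeroed)
  fixed <- variant_exponents_fixed[[id]]
  list(
    id = as.integer(id),
    zeroed = zeroed,
    exponents_fixed = fixed,
    n_free_coeffs = n_free,
    n_parameters = n_free + if (fixed) 0L else 2L
  )
}

coef_names <- c("p1", "p2", "p3", "p4", "q1", "q2", "q3")

#' Rational coupling surface
#'
#' One constrained variant of the normalized bivariate rational function
#' \deqn{f(X,Y) = \frac{p_1 XY + p_2 X + p_3 Y + p_4}{q_1 XY + q_2 X + q_3 Y + 1}.}
#' Coefficients zeroed by the variant's constraint mask must be zero (they
#' default to zero and are checked).
#'
#' @param variant Variant number, 1--9 (see [variant_spec()]).
#' @param p1,p2,p3,p4 Numerator coefficients, in the units of the modelled
#'   parameter.
#' @param q1,q2,q3 Denominator coefficients, dimensionless.
#'
#' @return An object of class `rational_surface`.
#' @export
#'
#' @examples
#' s <- rational_surface(7, p1 = 18.50, p4 = 0.765, q1 = 27.69)
#' eval_surface(s, X = 6.36, Y = 3.47)
rational_surface <- function(variant, p1 = 0, p2 = 0, p3 = 0, p4 = 0,
                             q1 = 0, q2 = 0, q3 = 0) {
  spec <- variant_spec(variant)
  coefs <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, q1 = q1, q2 = q2, q3 = q3)
  if (any(!is.finite(coefs))) stop_domain("Surface coefficients must be finite.")
  bad <- spec$zeroed[coefs[spec$zeroed] != 0]
  if (length(bad)) {
    stop_domain(sprintf(
      "Variant %d fixes %s at zero.", spec$id, paste(bad, collapse = ", ")
    ))
  }
  structure(c(as.list(coefs), list(variant = spec$id)),
            class = "rational_surface")
}

#' @export
print.rational_surface <- function(x, ...) {
  cat(sprintf(
    "<rational_surface> variant %d: f(X,Y) = (%g XY + %g X + %g Y + %g) / (%g XY + %g X + %g Y + 1)\n",
    x$variant, x$p1, x$p2, x$p3, x$p4, x$q1, x$q2, x$q3
  ))
  invisible(x)
}

as_rational_surface <- function(s) {
  if (inherits(s, "rational_surface")) return(s)
  stop_domain("`s` must be a `rational_surface` object.")
}

eval_surface_scalar <- function(s, X, Y) {
  if (is.infinite(X) && is.infinite(Y)) {
    if (s$q1 != 0) return(s$p1 / s$q1)
    if (s$p1 != 0) stop_singular("Surface diverges as X, Y -> Inf.")
    # XY terms absent; well defined only when the edge terms are absent too
    if (s$p2 == 0 && s$q2 == 0 && s$p3 == 0 && s$q3 == 0) return(s$p4)
    stop_singular("Path-dependent limit as X, Y -> Inf.")
  }
  if (is.infinite(X)) {
    cn <- s$p1 * Y + s$p2
    cd <- s$q1 * Y + s$q2
    if (cd != 0) return(cn / cd)
    if (cn != 0) stop_singular("Surface diverges as X -> Inf.")
    return((s$p3 * Y + s$p4) / (s$q3 * Y + 1))
  }
  if (is.infinite(Y)) {
    cn <- s$p1 * X + s$p3
    cd <- s$q1 * X + s$q3
    if (cd != 0) return(cn / cd)
    if (cn != 0) stop_singular("Surface diverges as Y -> Inf.")
    return((s$p2 * X + s$p4) / (s$q2 * X + 1))
  }
  den <- s$q1 * X * Y + s$q2 * X + s$q3 * Y + 1
  if (den == 0) stop_singular("Zero denominator: singular surface point.")
  (s$p1 * X * Y + s$p2 * X + s$p3 * Y + s$p4) / den
}

#' Evaluate a rational surface
#'
#' Evaluates `f(X, Y)` with explicit limit algebra at infinite arguments
#' (the image of a variable at the upper bound of its normalization), so
#' boundary behaviour is exact rather than a floating-point overflow.
#'
#' @param s A [rational_surface()].
#' @param X,Y Normalized covariates in \[0, Inf\] (vectorised, recycled).
#'
#' @return Surface values.
#' @export
eval_surface <- function(s, X, Y) {
  s <- as_rational_surface(s)
  if (any(X < 0, na.rm = TRUE) || any(Y < 0, na.rm = TRUE)) {
    stop_domain("Normalized covariates must be non-negative.")
  }
  n <- max(length(X), length(Y))
  X <- rep_len(X, n)
  Y <- rep_len(Y, n)
  if (all(is.finite(X)) && all(is.finite(Y))) {
    den <- s$q1 * X * Y + s$q2 * X + s$q3 * Y + 1
    if (any(den == 0)) stop_singular("Zero denominator: singular surface point.")
    return((s$p1 * X * Y + s$p2 * X + s$p3 * Y + s$p4) / den)
  }
  purrr::map2_dbl(X, Y, function(x, y) eval_surface_scalar(s, x, y))
}

#' Boundary profile of a rational surface
#'
#' Returns the univariate rational function obtained by pinning one
#' covariate at an edge of its normalized range: e.g. at `X = 0` the surface
#' reduces to \eqn{(p_3 Y + p_4)/(q_3 Y + 1)}, and at `X = Inf` to
#' \eqn{(p_1 Y + p_2)/(q_1 Y + q_2)}.
#'
#' @param s A [rational_surface()].
#' @param edge One of `"X=0"`, `"X=Inf"`, `"Y=0"`, `"Y=Inf"`.
#'
#' @return A function of the remaining covariate.
#' @export
surface_limit <- function(s, edge = c("X=0", "X=Inf", "Y=0", "Y=Inf")) {
  s <- as_rational_surface(s)
  edge <- match.arg(edge)
  switch(edge,
    "X=0"   = function(Y) eval_surface(s, 0, Y),
    "X=Inf" = function(Y) eval_surface(s, Inf, Y),
    "Y=0"   = function(X) eval_surface(s, X, 0),
    "Y=Inf" = function(X) eval_surface(s, X, Inf)
  )
}

# model library ----------------------------------------------------------

#' The 25-pair model library
#'
#' A coupled reduced-order model assigns one rational surface to each of its
#' two coupled parameters. Out of the 81 conceivable variant pairs, the
#' library retains 25: matched pairs `(v, v)` for `v = 1..8`, pairs with a
#' constant second surface `(v, 9)` for `v = 1..8`, and a constant first
#' surface `(9, w)` for `w = 1..9`.
#'
#' @return A tibble with columns `variant1` and `variant2` (25 rows).
#' @export
#'
#' @examples
#' model_library()
model_library <- function() {
  pairs <- rbind(
    cbind(1:8, 1:8),
    cbind(1:8, 9L),
    cbind(9L, 1:9)
  )
  tibble::tibble(variant1 = as.integer(pairs[, 1]),
                 variant2 = as.integer(pairs[, 2]))
}

pair_in_library <- function(variant1, variant2) {
  lib <- model_library()
  any(lib$variant1 == variant1 & lib$variant2 == variant2)
}

pair_exponents_free <- function(variant1, variant2) {
  !(variant_exponents_fixed[variant1] & variant_exponents_fixed[variant2])
}

#' Parameter count of a model pair
#'
#' Total number of fitted parameters for a pair of surfaces: free
#' coefficients of each surface, plus the two shared exponents whenever at
#' least one member leaves them free, plus any scalar constants fitted
#' alongside (e.g. the Kawakita pressure parameter `b`, or the recovery
#' exponent `n`).
#'
#' @param variant1,variant2 Variant numbers of the two surfaces (vectorised).
#' @param n_constants Number of scalar constants fitted alongside.
#'
#' @return Integer parameter count(s).
#' @export
#'
#' @examples
#' n_parameters(7, 7, n_constants = 1) # 9
#' n_parameters(4, 9, n_constants = 1) # 7
n_parameters <- function(variant1, variant2, n_constants = 0L) {
  if (any(!variant1 %in% 1:9) || any(!variant2 %in% 1:9)) {
    stop_domain("Variant numbers must be in 1..9.")
  }
  free1 <- 7L - lengths(variant_zeroed)[variant1]
  free2 <- 7L - lengths(variant_zeroed)[variant2]
  exps <- ifelse(pair_exponents_free(variant1, variant2), 2L, 0L)
  as.integer(free1 + free2 + exps + n_constants)
}
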