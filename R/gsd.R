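# Bimodal Weibull granule size distribution and packing-model covariates.
# Sizes are in micrometres throughout.

#' Bimodal Weibull granule size distribution
#'
#' Five-parameter Weibull mixture describing the granule size distribution
#' produced by ribbon milling: a small mode (fraction `alpha`, scale
#' `lambda1`, shape `k1`) and a large mode (`lambda2`, `k2`). Mode 1 must be
#' the small mode, i.e. its mean must not exceed the large-mode mean.
#'
#' @param alpha Fraction of the small mode, in \[0, 1\].
#' @param lambda1,lambda2 Scale parameters, um.
#' @param k1,k2 Shape parameters, dimensionless.
#'
#' @return An object of class `bimodal_weibull`.
#' @export
#'
#' @examples
#' gsd <- bimodal_weibull(0.46, 541, 2.24, 1170, 4.98)
#' gsd_mean(gsd)
bimodal_weibull <- function(alpha, lambda1, k1, lambda2, k2) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop_domain("`alpha` must lie in [0, 1].")
  }
  check_positive(lambda1, "lambda1")
  check_positive(lambda2, "lambda2")
  check_positive(k1, "k1")
  check_positive(k2, "k2")
  gsd <- structure(
    list(alpha = alpha, lambda1 = lambda1, k1 = k1,
         lambda2 = lambda2, k2 = k2),
    class = "bimodal_weibull"
  )
  mm <- gsd_mode_means(gsd)
  if (mm[[1]] > mm[[2]]) {
    stop_domain("Mode 1 must be the small mode (mu1 <= mu2).")
  }
  gsd
}

#' @export
print.bimodal_weibull <- function(x, ...) {
  cat(sprintf(
    "<bimodal_weibull> alpha = %g | small: (lambda = %g um, k = %g) | large: (lambda = %g um, k = %g)\n",
    x$alpha, x$lambda1, x$k1, x$lambda2, x$k2
  ))
  cat(sprintf("  mean granule size: %.1f um\n", gsd_mean(x)))
  invisible(x)
}

as_bimodal_weibull <- function(gsd) {
  if (inherits(gsd, "bimodal_weibull")) return(gsd)
  stop_domain("`gsd` must be a `bimodal_weibull` object.")
}

#' Density of the bimodal Weibull mixture
#'
#' @param x Granule sizes, um (non-negative, vectorised).
#' @param gsd A [bimodal_weibull()].
#'
#' @return Mixture density in 1/um.
#' @export
gsd_density <- function(x, gsd) {
  gsd <- as_bimodal_weibull(gsd)
  if (any(x < 0)) stop_domain("`x` must be non-negative.")
  gsd$alpha * stats::dweibull(x, shape = gsd$k1, scale = gsd$lambda1) +
    (1 - gsd$alpha) * stats::dweibull(x, shape = gsd$k2, scale = gsd$lambda2)
}

#' Component means and mean granule size
#'
#' `gsd_mode_means()` returns the means of the two Weibull components,
#' \eqn{\mu_i = \lambda_i \Gamma(1 + 1/k_i)}; `gsd_mean()` the
#' mixture-weighted mean \eqn{\mu_{GSD} = \alpha\mu_1 + (1-\alpha)\mu_2}.
#'
#' @param gsd A [bimodal_weibull()].
#'
#' @return `gsd_mode_means()`: a named numeric vector `c(mu1, mu2)` in um;
#'   `gsd_mean()`: a single mean size in um.
#' @export
gsd_mode_means <- function(gsd) {
  if (!inherits(gsd, "bimodal_weibull")) gsd <- as_bimodal_weibull(gsd)
  c(mu1 = gsd$lambda1 * gamma(1 + 1 / gsd$k1),
    mu2 = gsd$lambda2 * gamma(1 + 1 / gsd$k2))
}

#' @rdname gsd_mode_means
#' @export
gsd_mean <- function(gsd) {
  gsd <- as_bimodal_weibull(gsd)
  mm <- gsd_mode_means(gsd)
  unname(gsd$alpha * mm[[1]] + (1 - gsd$alpha) * mm[[2]])
}

#' Sample granule sizes from the mixture
#'
#' Draws a Bernoulli(`alpha`) component label per granule, then a Weibull
#' size from the chosen mode.
#'
#' @param gsd A [bimodal_weibull()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#'
#' @return Numeric vector of `n` sizes, um.
#' @export
gsd_sample <- function(gsd, n, seed = NULL) {
  gsd <- as_bimodal_weibull(gsd)
  if (n < 1) stop_domain("`n` must be at least 1.")
  draw <- function() {
    small <- stats::rbinom(n, 1L, gsd$alpha) == 1L
    out <- numeric(n)
    out[small] <- stats::rweibull(sum(small), shape = gsd$k1, scale = gsd$lambda1)
    out[!small] <- stats::rweibull(sum(!small), shape = gsd$k2, scale = gsd$lambda2)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Packing-model covariates of a granule size distribution
#'
#' The packing-fraction weight model uses two normalized covariates of the
#' bimodal GSD: \eqn{X = (1-\alpha)(1 - \mu_1^3/\mu_2^3)} and
#' \eqn{Y = \alpha}, both in \[0, 1\] whenever mode 1 is the small mode.
#'
#' @param gsd A [bimodal_weibull()].
#'
#' @return A named numeric vector `c(X, Y)`.
#' @export
packing_covariates <- function(gsd) {
  gsd <- as_bimodal_weibull(gsd)
  mm <- gsd_mode_means(gsd)
  if (mm[[1]] > mm[[2]]) stop_domain("Mode ordering violated (mu1 > mu2).")
  c(X = (1 - gsd$alpha) * (1 - mm[[1]]^3 / mm[[2]]^3), Y = gsd$alpha)
}

# data-frame verbs -------------------------------------------------------

gsd_from_row <- function(row) {
  bimodal_weibull(row$alpha, row$lambda1, row$k1, row$lambda2, row$k2)
}

#' Add GSD summaries to a batch table
#'
#' `add_gsd_means()` appends `mu1`, `mu2` and `mu_gsd` (um) to a data frame
#' with columns `alpha`, `lambda1`, `k1`, `lambda2`, `k2`;
#' `add_packing_covariates()` appends the packing covariates `X_pack` and
#' `Y_pack`. Both recompute from the Weibull parameters rather than trusting
#' any printed means carried along as metadata.
#'
#' @param batches A data frame of granule batches, one row per batch.
#'
#' @return The input as a tibble with the new columns appended.
#' @export
#'
#' @examples
#' granule_batches() |> add_packing_covariates()
add_gsd_means <- function(batches) {
  batches <- tibble::as_tibble(batches)
  mu1 <- batches$lambda1 * gamma(1 + 1 / batches$k1)
  mu2 <- batches$lambda2 * gamma(1 + 1 / batches$k2)
  dplyr::mutate(
    batches,
    mu1 = mu1, mu2 = mu2,
    mu_gsd = .data$alpha * mu1 + (1 - .data$alpha) * mu2
  )
}

#' @rdname add_gsd_means
#' @export
add_packing_covariates <- function(batches) {
  batches <- add_gsd_means(batches)
  if (any(batches$mu1 > batches$mu2)) {
    stop_domain("Mode ordering violated (mu1 > mu2) in at least one batch.")
  }
  dplyr::mutate(
    batches,
    X_pack = (1 - .data$alpha) * (1 - .data$mu1^3 / .data$mu2^3),
    Y_pack = .data$alpha
  )
}
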