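# ggplot2 views of granule size distributions, packing surfaces and fits.

#' Plot granule size distributions
#'
#' Density curves of the bimodal Weibull size distributions of one or more
#' granule batches.
#'
#' @param batches A batch tibble (see [granule_batches()]).
#' @param x_max Upper plotting limit, um.
#'
#' @return A ggplot object.
#' @export
plot_gsd <- function(batches = granule_batches(), x_max = 2000) {
  batches <- tibble::as_tibble(batches)
  x <- seq(0, x_max, length.out = 400)
  curves <- purrr::map(seq_len(nrow(batches)), function(i) {
    row <- batches[i, ]
    tibble::tibble(
      batch = factor(sprintf("%g bar / %g mm", row$roll_pressure_bar,
                             row$roll_gap_mm)),
      x = x,
      density = gsd_density(x, gsd_from_row(row))
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(.data$x, .data$density,
                                       colour = .data$batch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "granule size (µm)", y = "density (1/µm)",
                  colour = "batch") +
    ggplot2::theme_minimal()
}

#' Plot the packing-fraction surface
#'
#' Packing fraction against the small-mode fraction for several mode size
#' ratios, the view in which the packing maximum near alpha ~ 0.7 is
#' visible.
#'
#' @param weight Packing-surface coefficients (list with `p4`, `q1`, `q2`).
#' @param size_ratios Mode size ratios (small over large) to draw.
#'
#' @return A ggplot object.
#' @export
plot_packing_surface <- function(weight = reference_parameters()$weight,
                                 size_ratios = c(0.2, 0.4, 0.6, 0.8)) {
  alpha <- seq(0, 1, length.out = 201)
  grid <- tidyr::expand_grid(alpha = alpha, ratio = size_ratios) |>
    dplyr::mutate(
      X = (1 - .data$alpha) * (1 - .data$ratio^3),
      phi = packing_fraction(.data$X, .data$alpha, weight$p4, weight$q1,
                             weight$q2)
    )
  ggplot2::ggplot(grid, ggplot2::aes(.data$alpha, .data$phi,
                                     colour = factor(.data$ratio))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(alpha), y = expression(phi),
                  colour = expression(mu[1] / mu[2])) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_rom Observed-versus-predicted plot for a fitted model.
#' @param object A `rom_fit`.
#' @param ... Unused.
#' @export
autoplot.rom_fit <- function(object, ...) {
  df <- tibble::tibble(observed = object$data$obs, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s fit: R² = %.3f", object$cqa, object$r_squared),
      x = "observed", y = "predicted"
    ) +
    ggplot2::theme_minimal()
}
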