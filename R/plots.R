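#' Plot a free-energy surface
#'
#' Raster of F(chi, Delta) in epsilon units, empty bins blank.
#'
#' @param object a `free_energy_surface`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot free_energy_surface
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  grid <- expand.grid(chi = object$chi_mid, delta = object$delta_mid)
  grid$F <- as.vector(object$F)
  grid <- grid[!is.na(grid$F), , drop = FALSE]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$chi, y = .data$delta,
                                     fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(F / epsilon)) +
    ggplot2::labs(x = expression(chi), y = expression(Delta),
                  title = sprintf("Free energy at kT = %g", object$kT)) +
    ggplot2::theme_minimal()
}

#' Plot a melting curve and (optionally) its fitted model
#'
#' @param object an `unfold_fit` or a `melting_curve`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot unfold_fit
#' @export
autoplot.unfold_fit <- function(object, ...) {
  df <- data.frame(temperature = object$curve$temperature,
                   signal = object$curve$signal,
                   fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 1,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = sprintf("Temperature (%s)", attr(object$curve, "unit")),
                  y = "Mean residue ellipticity (deg cm2/dmol)",
                  title = sprintf("%s unfolding fit", object$model)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.unfold_fit
#' @method autoplot melting_curve
#' @export
autoplot.melting_curve <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = .data$temperature, y = .data$signal)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::labs(x = sprintf("Temperature (%s)", attr(object, "unit")),
                  y = "Signal") +
    ggplot2::theme_minimal()
}

#' Plot a contact probability or covariance matrix
#'
#' @param m a matrix (e.g. the `matrix` component of
#'   [contact_probability_matrix()] or a [contact_covariance()] result).
#' @param name fill-scale label.
#' @return a ggplot object.
#' @export
plot_contact_matrix <- function(m, name = "value") {
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.vector(m)
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = name, limits = c(-1, 1) *
                                    max(abs(df$value))) +
    ggplot2::labs(x = "residue / contact index", y = "residue / contact index") +
    ggplot2::theme_minimal()
}
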