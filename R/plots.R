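# ggplot2 displays for spectra, fits and grouped summaries.

#' Plot leaf spectra
#'
#' Reflectance and transmittance against wavelength, one facet per
#' quantity, coloured by `sample_id` when present.
#'
#' @param spectra A spectrum tibble (one sample or tall).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  long <- tidyr::pivot_longer(spectra, c("reflectance", "transmittance"),
                              names_to = "quantity", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength_nm,
                                          y = .data$value))
  p <- if (!is.null(long$sample_id)) {
    p + ggplot2::geom_line(ggplot2::aes(group = .data$sample_id,
                                        colour = .data$sample_id),
                           show.legend = length(unique(long$sample_id)) <= 8)
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~quantity, ncol = 1) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.leaf_fit
#' @export
plot_fit <- function(object, ...) autoplot.leaf_fit(object, ...)

#' Plot a spectral fit
#'
#' Overlays the fitted plate-model reflectance and transmittance on the
#' measurements across the fit window.
#'
#' @param object A `leaf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leaf_fit
#' @export
autoplot.leaf_fit <- function(object, ...) {
  aug <- augment(object)
  long <- dplyr::bind_rows(
    tibble::tibble(wavelength_nm = aug$wavelength_nm, quantity = "reflectance",
                   observed = aug$reflectance,
                   fitted = aug$.fitted_reflectance),
    tibble::tibble(wavelength_nm = aug$wavelength_nm,
                   quantity = "transmittance",
                   observed = aug$transmittance,
                   fitted = aug$.fitted_transmittance)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength_nm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~quantity, ncol = 1) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL,
                  title = "Plate-model fit (red) vs measurement") +
    ggplot2::theme_minimal()
}

#' Plot grouped pigment or index time courses
#'
#' Group means against sampling day, coloured by light spectrum and
#' faceted by cultivar and PFD — the layout used for treatment time
#' series.
#'
#' @param series Output of [pigment_ratio_series()] or any tibble with
#'   `day`, a value column, and the treatment factors.
#' @param value Name of the value column (default `mean_ratio`).
#' @return A ggplot object.
#' @export
plot_group_series <- function(series, value = "mean_ratio") {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$day, y = .data[[value]],
                                       colour = .data$spectrum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(cultivar ~ pfd, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "day after treatment start") +
    ggplot2::theme_minimal()
}
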