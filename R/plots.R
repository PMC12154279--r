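#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot metabolite or ratio maps
#'
#' Faceted raster display of the per-metabolite (or per-ratio) maps.
#'
#' @param object a `metabolite_maps` or `ratio_maps` object
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.metabolite_maps <- function(object, ...) {
  df <- tidy.metabolite_maps(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~metabolite) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "a.u.")
}

#' Plot an ROI-averaged (or single-voxel) spectrum
#'
#' @param spectrum complex spectrum with a `freq_hz` attribute, as
#'   returned by [average_roi_spectrum()]
#' @param mode `"real"` (absorption) or `"magnitude"`
#' @return a ggplot
#' @export
plot_spectrum <- function(spectrum, mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  freq <- attr(spectrum, "freq_hz")
  stopifnot(!is.null(freq))
  y <- if (mode == "real") Re(spectrum) else Mod(spectrum)
  df <- tibble::tibble(freq_hz = freq, signal = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency offset from pyruvate (Hz)",
                  y = paste0(mode, " signal (a.u.)"))
}

#' Plot a phantom label map
#'
#' @param object a [build_phantom()] result
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.phantom <- function(object, ...) {
  lab <- object$label_map
  codes <- object$labels
  df <- tibble::tibble(
    y = rep(seq_len(nrow(lab)), ncol(lab)),
    x = rep(seq_len(ncol(lab)), each = nrow(lab)),
    compartment = factor(names(codes)[match(as.vector(lab), codes)],
                         levels = names(codes))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
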