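#' Plot a spectral library
#'
#' One absorption curve per chromophore over the grid; the gap between the
#' laser bands is left unconnected.
#'
#' @param object A `paf_library`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paf_library <- function(object, ...) {
  tb <- as_tibble(object)
  long <- tidyr::pivot_longer(tb, -"wavelength_nm",
    names_to = "chromophore", values_to = "absorption"
  )
  # band id so geom_line does not bridge the inter-band gap
  long$band <- vapply(long$wavelength_nm, function(w) {
    which(vapply(
      object$grid$band_edges,
      function(b) w >= b[1] && w <= b[2], logical(1)
    ))[1]
  }, integer(1))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$absorption,
    color = .data$chromophore,
    group = interaction(.data$chromophore, .data$band)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wavelength (nm)", y = "absorption (raw units)",
      color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot training history of a fitted model
#'
#' @param object A `paf_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation Huber loss per epoch.
#' @export
autoplot.paf_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "split", values_to = "loss"
  )
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss, color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "Huber loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Parity plot of predicted vs true concentrations
#'
#' Pools all chromophore components; points may be colored by a covariate
#' such as SNR or fluence severity.
#'
#' @param truth,pred n x N matrices of true and predicted fractions.
#' @param color Optional length-n vector (recycled across chromophores)
#'   used as the color aesthetic.
#' @param color_name Legend title for `color`.
#' @return A ggplot.
#' @export
plot_parity <- function(truth, pred, color = NULL, color_name = NULL) {
  T_ <- as_conc_matrix(truth)
  P_ <- zero_fill_undefined(as_conc_matrix(pred))
  df <- tibble(
    true = as.vector(T_),
    predicted = as.vector(P_)
  )
  if (!is.null(color)) df$color <- rep(color, ncol(T_))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$true, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey40")
  p <- if (is.null(color)) {
    p + ggplot2::geom_point(alpha = 0.2, size = 0.4)
  } else {
    p + ggplot2::geom_point(
      ggplot2::aes(color = .data$color),
      alpha = 0.4, size = 0.4
    ) +
      ggplot2::labs(color = color_name)
  }
  p + ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true concentration", y = "predicted concentration") +
    ggplot2::theme_minimal()
}

#' Plot stratified average absolute error curves
#'
#' @param tbl Output of [aae()] with a stratifier (uses `stratum_mid` when
#'   present).
#' @param x_name Axis label for the stratifier.
#' @return A ggplot, one line per chromophore.
#' @export
plot_aae <- function(tbl, x_name = "stratum") {
  xvar <- if ("stratum_mid" %in% names(tbl)) "stratum_mid" else "stratum"
  ggplot2::ggplot(tbl, ggplot2::aes(
    .data[[xvar]], .data$aae,
    color = .data$chromophore, group = .data$chromophore
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = x_name, y = "average absolute error", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a concentration map
#'
#' Per-chromophore fraction maps (plus sO2) as rasters; masked pixels are
#' blank.
#'
#' @param object A `paf_concentration_map`.
#' @param channels Which channels to draw (default all fractions + sO2).
#' @param ... Unused.
#' @return A ggplot faceted by channel.
#' @export
autoplot.paf_concentration_map <- function(object,
                                           channels = c(attr(object, "chromophores"), "so2"),
                                           ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("y", "x", "masked", channels)],
    dplyr::all_of(channels),
    names_to = "channel", values_to = "fraction"
  )
  long$fraction[long$masked] <- NA_real_
  long$channel <- factor(long$channel, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "black", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "fraction",
      title = paste0(attr(object, "method"), " concentration map")
    ) +
    ggplot2::theme_minimal()
}
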