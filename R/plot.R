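#' Plot a lobe amplitude spectrum
#'
#' @param object A `loco_efa` fit.
#' @param max_mode Largest mode shown (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loco_efa <- function(object, max_mode = NULL, ...) {
  sp <- object$spectrum
  if (!is.null(max_mode)) sp <- sp[sp$l <= max_mode, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$l, y = .data$L)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "lobe mode l", y = expression(L[l]),
                  title = "Lobe contribution spectrum") +
    ggplot2::theme_minimal()
}

#' Plot an XOR / marginal-difference profile
#'
#' @param object An `xor_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xor_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("xor", "marginal"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(stats::na.omit(long),
                  ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "modes used (n)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a label image
#'
#' @param object A `label_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_image <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$id <- as.vector(t(m))
  df$y <- nrow(m) - df$row + 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$y,
                                   fill = factor(.data$id))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a contour (and optionally a reconstruction over it)
#'
#' @param contour A contour tibble.
#' @param reconstruction Optional second contour drawn on top.
#' @return A ggplot object.
#' @export
plot_contour <- function(contour, reconstruction = NULL) {
  close_ct <- function(ct) {
    tibble::tibble(x = c(ct$x, ct$x[1]), y = c(ct$y, ct$y[1]))
  }
  p <- ggplot2::ggplot(close_ct(contour), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(reconstruction)) {
    p <- p + ggplot2::geom_path(data = close_ct(reconstruction),
                                colour = "firebrick", linetype = 2)
  }
  p
}
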