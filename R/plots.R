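# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MSD series
#'
#' MSD against time with the free-diffusion reference line
#' \eqn{4 D_p t} for comparison.
#'
#' @param object An `msd_series` from [simulate_tracers()].
#' @param D_p Reference unhindered diffusivity in cm²/s (default
#'   `1e-6`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_series <- function(object, D_p = 1e-6, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$msd_nm2)) +
    ggplot2::geom_abline(slope = 4 * D_p * 1e14, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(MSD ~ (nm^2)),
                  title = "Mean squared displacement",
                  subtitle = "dashed: unhindered 4 D[p] t") +
    ggplot2::theme_minimal()
}

#' Plot a binary domain
#'
#' @param object A [binary_domain()].
#' @param ... Unused.
#' @return A ggplot raster of pore (white) and cell (black) sites.
#' @export
autoplot.binary_domain <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$pore)), times = ncol(object$pore)),
    col = rep(seq_len(ncol(object$pore)), each = nrow(object$pore)),
    pore = as.vector(object$pore))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pore)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white"),
                               labels = c(`FALSE` = "cell", `TRUE` = "pore"),
                               name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a BTV calibration sweep
#'
#' Relative diffusivity `D/D_GT` against the binarization threshold, with
#' the unity line and the interpolated optimal BTV marked.
#'
#' @param object A `btv_sweep` from [btv_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.btv_sweep <- function(object, ...) {
  opt <- attr(object, "optimal_btv")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$btv, y = .data$d_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "brightness threshold value (BTV)",
                  y = expression(D / D[GT]),
                  title = "Functional calibration of the binarization threshold") +
    ggplot2::theme_minimal()
  if (!is.na(opt)) {
    p <- p + ggplot2::geom_vline(xintercept = opt, colour = "firebrick",
                                 linetype = "dotted")
  }
  p
}

#' Plot a diffusivity heatmap
#'
#' @param object A `diffusion_heatmap`.
#' @param what `"d_relative"` (default) or `"porosity"`.
#' @param ... Unused.
#' @return A ggplot raster at unit-cell resolution.
#' @export
autoplot.diffusion_heatmap <- function(object, what = c("d_relative",
                                                        "porosity"), ...) {
  what <- match.arg(what)
  df <- tidy(object)
  fill <- if (what == "d_relative") "d_relative" else "porosity"
  lab <- if (what == "d_relative") expression(D / D[p]) else "porosity"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "Spatially resolved local diffusivity") +
    ggplot2::theme_minimal()
}

#' Porosity-diffusivity collapse plot
#'
#' Scatter of local relative diffusivity against local porosity pooled
#' over subdomains (and over heatmaps, e.g. sparse and dense regions
#' together).
#'
#' @param table A tibble from [porosity_diffusivity_table()].
#' @return A ggplot.
#' @export
plot_porosity_diffusivity <- function(table) {
  stopifnot(all(c("porosity", "d_relative") %in% names(table)))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$porosity,
                                      y = .data$d_relative)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "local porosity", y = expression(D / D[p]),
                  title = "Porosity-diffusivity collapse") +
    ggplot2::theme_minimal()
}
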