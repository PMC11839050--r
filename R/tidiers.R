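# broom-style tidy()/glance() methods for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a diffusivity estimate
#'
#' @param x A `diffusivity_estimate` from [run_replicates()] or
#'   [estimate_diffusivity()].
#' @param ... Unused.
#' @return A tibble with one row per replicate: `replicate`, `seed`,
#'   `D_cm2_s`, `D_relative`.
#' @export
tidy.diffusivity_estimate <- function(x, ...) {
  x$replicate_values
}

#' @rdname tidy.diffusivity_estimate
#' @return `glance()` returns a one-row tibble with the replicate-averaged
#'   `D_cm2_s`, `D_relative`, `dispersion`, the fit window and run sizes.
#' @export
glance.diffusivity_estimate <- function(x, ...) {
  tibble::tibble(
    D_cm2_s = x$D,
    D_relative = x$D_relative,
    dispersion = x$dispersion,
    n_replicates = nrow(x$replicate_values),
    n_particles = x$config$n_particles,
    t_fit_start_s = x$fit_window[1],
    t_end_s = x$fit_window[2])
}

#' Tidy a BTV calibration sweep
#'
#' @param x A `btv_sweep` from [btv_sweep()].
#' @param ... Unused.
#' @return `tidy()`: the sweep tibble (`btv`, `D_cm2_s`, `d_ratio`);
#'   `glance()`: one row with `optimal_btv`, `d_gt_cm2_s`, `n_btv`.
#' @export
tidy.btv_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.btv_sweep
#' @export
glance.btv_sweep <- function(x, ...) {
  tibble::tibble(
    optimal_btv = attr(x, "optimal_btv"),
    d_gt_cm2_s = attr(x, "d_gt"),
    d_gt_relative = attr(x, "d_gt_relative"),
    n_btv = nrow(x))
}

#' Tidy a diffusivity heatmap
#'
#' @param x A `diffusion_heatmap` from [diffusion_heatmap()].
#' @param ... Unused.
#' @return `tidy()`: a long tibble with one row per unit cell (`row`,
#'   `col`, 0-based cell indices; `x_um`, `y_um` cell centres; `d_relative`;
#'   `porosity`; `n_overlap`). `glance()`: one row of grid metadata.
#' @export
tidy.diffusion_heatmap <- function(x, ...) {
  nr <- x$n_cells[1]; nc <- x$n_cells[2]
  tidyr::expand_grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L) |>
    dplyr::mutate(
      x_um = (col + 0.5) * x$stride_um,
      y_um = (row + 0.5) * x$stride_um,
      d_relative = as.vector(t(x$local_d))[row * nc + col + 1L],
      porosity = as.vector(t(x$local_porosity))[row * nc + col + 1L],
      n_overlap = as.vector(t(x$overlap_count))[row * nc + col + 1L])
}

#' @rdname tidy.diffusion_heatmap
#' @export
glance.diffusion_heatmap <- function(x, ...) {
  tibble::tibble(
    n_subdomains = nrow(x$subdomains),
    n_cells = prod(x$n_cells),
    window_um = x$window_um,
    stride_um = x$stride_um,
    mean_d_relative = mean(x$local_d),
    mean_porosity = mean(x$local_porosity))
}
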