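# Higher-level transport analyses: staggered subdomain tiling, local
# diffusivity heatmaps with overlap averaging, brightness-threshold (BTV)
# calibration sweeps against ground truth, porosity-diffusivity tables.

# convert a physical length in um to whole pixels at the domain spacing
um_to_px <- function(length_um, spacing_nm, what) {
  px <- length_um * 1000 / spacing_nm
  if (abs(px - round(px)) > 1e-9) {
    rlang::abort(sprintf(
      "%s of %g um is not a whole number of pixels at %g nm spacing",
      what, length_um, spacing_nm))
  }
  as.integer(round(px))
}

#' Staggered subdomain tiling
#'
#' Origins of all square analysis windows of side `window_um` placed every
#' `stride_um` such that the window lies entirely inside the domain, in
#' row-major order. The standard protocol discretises a 10 x 10 µm² domain
#' into 81 2 x 2 µm² subdomains staggered by 1 µm.
#'
#' @param domain A [binary_domain()].
#' @param window_um Subdomain edge length in µm (default 2).
#' @param stride_um Stagger between neighbouring subdomains in µm
#'   (default 1).
#' @return A tibble with 0-based pixel origins `row_px`, `col_px` and the
#'   per-subdomain `porosity`; attributes `window_px` and `stride_px`.
#' @examples
#' dom <- generate_canonical("empty", dim = c(500, 500))
#' nrow(tile_subdomains(dom))  # 3 positions per axis -> 9
#' @export
tile_subdomains <- function(domain, window_um = 2, stride_um = 1) {
  stopifnot(inherits(domain, "binary_domain"))
  win <- um_to_px(window_um, domain$spacing_nm, "window")
  stride <- um_to_px(stride_um, domain$spacing_nm, "stride")
  d <- dim(domain$pore)
  if (win > d[1] || win > d[2]) {
    rlang::abort(sprintf("window (%d px) exceeds domain extent %d x %d",
                         win, d[1], d[2]))
  }
  if (stride < 1) rlang::abort("stride must be at least one pixel")
  rows <- seq(0L, d[1] - win, by = stride)
  cols <- seq(0L, d[2] - win, by = stride)
  grid <- tidyr::expand_grid(row_px = rows, col_px = cols)
  grid$porosity <- purrr::map2_dbl(grid$row_px, grid$col_px, function(r, c) {
    mean(domain$pore[(r + 1):(r + win), (c + 1):(c + win)])
  })
  attr(grid, "window_px") <- win
  attr(grid, "stride_px") <- stride
  grid
}

#' Spatially resolved diffusivity heatmap
#'
#' Runs a replicate-averaged diffusion simulation in every staggered
#' subdomain (each treated as its own mirrored lattice domain), then
#' overlap-averages onto a grid of stride-sized unit cells: a unit cell's
#' value is the mean relative diffusivity of every subdomain that fully
#' contains it — 4 subdomains in the interior, 2 on edges, 1 at corners.
#' A 10 x 10 µm² domain with 2 µm windows and 1 µm stagger yields 81
#' subdomains and exactly 100 overlap-averaged local diffusivities. A
#' porosity grid is computed identically from per-subdomain porosities.
#' For domains whose extent is not a whole number of windows, as many full
#' windows as fit are tiled and trailing remainder pixels are excluded
#' (recorded in the result's `n_cells` metadata).
#'
#' @param domain A [binary_domain()].
#' @param config A [sim_config()]; subdomain k runs with seeds offset by
#'   `(k - 1) * replicates` so replicate streams never overlap.
#' @param window_um,stride_um Tiling parameters in µm (defaults 2 and 1).
#' @return A `diffusion_heatmap` object with fields `local_d` and
#'   `local_porosity` (matrices at unit-cell resolution), `subdomains`
#'   (tibble of per-subdomain origin, porosity, `D_cm2_s`, `d_relative`),
#'   `window_um`, `stride_um`, `config`. See [tidy()][generics::tidy] and
#'   [autoplot.diffusion_heatmap()].
#' @export
diffusion_heatmap <- function(domain, config = sim_config(), window_um = 2,
                              stride_um = 1) {
  stopifnot(inherits(domain, "binary_domain"))
  tiles <- tile_subdomains(domain, window_um, stride_um)
  win <- attr(tiles, "window_px")
  stride <- attr(tiles, "stride_px")
  if (win %% stride != 0) {
    rlang::abort("window must be a whole multiple of stride for overlap averaging")
  }
  w_cells <- win %/% stride

  sub <- dplyr::mutate(
    tiles,
    est = purrr::pmap(list(row_px, col_px, dplyr::row_number()),
                      function(r, c, k) {
      sub_pore <- domain$pore[(r + 1):(r + win), (c + 1):(c + win)]
      sub_dom <- binary_domain(sub_pore, spacing_nm = domain$spacing_nm)
      sub_cfg <- config
      sub_cfg$seed <- config$seed + (k - 1L) * config$replicates
      if (!any(sub_pore)) {
        return(list(D = 0, d_rel = 0))
      }
      est <- run_replicates(sub_dom, sub_cfg)
      list(D = est$D, d_rel = est$D_relative)
    }),
    D_cm2_s = purrr::map_dbl(est, "D"),
    d_relative = purrr::map_dbl(est, "d_rel"))
  sub$est <- NULL

  # overlap averaging on stride-sized unit cells, full containment only
  n_cells_r <- max(sub$row_px) %/% stride + w_cells
  n_cells_c <- max(sub$col_px) %/% stride + w_cells
  acc_d <- matrix(0, n_cells_r, n_cells_c)
  acc_p <- matrix(0, n_cells_r, n_cells_c)
  cnt <- matrix(0L, n_cells_r, n_cells_c)
  for (k in seq_len(nrow(sub))) {
    ir <- sub$row_px[k] %/% stride + seq_len(w_cells)
    ic <- sub$col_px[k] %/% stride + seq_len(w_cells)
    acc_d[ir, ic] <- acc_d[ir, ic] + sub$d_relative[k]
    acc_p[ir, ic] <- acc_p[ir, ic] + sub$porosity[k]
    cnt[ir, ic] <- cnt[ir, ic] + 1L
  }
  structure(
    list(local_d = acc_d / cnt, local_porosity = acc_p / cnt,
         overlap_count = cnt, subdomains = sub,
         window_um = window_um, stride_um = stride_um,
         n_cells = c(n_cells_r, n_cells_c), config = config),
    class = "diffusion_heatmap")
}

#' @export
print.diffusion_heatmap <- function(x, ...) {
  cat(sprintf(
    "<diffusion_heatmap> %d subdomains (%g um window, %g um stride) -> %d x %d unit cells\n",
    nrow(x$subdomains), x$window_um, x$stride_um, x$n_cells[1], x$n_cells[2]))
  cat(sprintf("  local D/D_p in [%.3g, %.3g], porosity in [%.3f, %.3f]\n",
              min(x$local_d), max(x$local_d), min(x$local_porosity),
              max(x$local_porosity)))
  invisible(x)
}

# abscissa of the first crossing of y through `target` over increasing x,
# with linear interpolation between bracketing points; NA when no crossing
interp_crossing <- function(x, y, target = 1) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  dy <- y - target
  if (dy[1] == 0) return(x[1])
  for (i in seq_len(length(x) - 1)) {
    if (dy[i + 1] == 0) return(x[i + 1])
    if (dy[i] * dy[i + 1] < 0) {
      return(x[i] + (target - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i]))
    }
  }
  NA_real_
}

#' Brightness-threshold calibration sweep
#'
#' Computes the functional-accuracy calibration curve: the domain
#' diffusivity after binarizing a grayscale segmentation map at each
#' threshold (BTV), expressed relative to the ground-truth diffusivity
#' `D_GT` from a manually labelled domain. The optimal BTV is the abscissa
#' where the ratio crosses 1 (linearly interpolated between the bracketing
#' sweep points, first crossing in increasing BTV order); it is `NA` when
#' the sweep never crosses 1.
#'
#' @param gray A [gray_image()] (cell probability or gradient-flow map
#'   rendered as an image), same dimensions as `gt`.
#' @param gt Ground-truth [binary_domain()] (e.g. from [mask_to_domain()]).
#' @param btv_values Increasing integer thresholds to sweep (default
#'   `seq(0, 255, by = 5)`).
#' @param config A [sim_config()].
#' @param cell_below_threshold Binarization polarity (default `TRUE`).
#' @return A `btv_sweep` tibble with columns `btv`, `D_cm2_s`, `d_ratio`,
#'   and attributes `d_gt` (cm²/s) and `optimal_btv`. [glance()] gives the
#'   one-row summary; [autoplot()] draws the calibration curve.
#' @export
btv_sweep <- function(gray, gt, btv_values = seq(0, 255, by = 5),
                      config = sim_config(), cell_below_threshold = TRUE) {
  stopifnot(inherits(gray, "gray_image"), inherits(gt, "binary_domain"))
  if (!identical(dim(gray$pixels), dim(gt$pore))) {
    rlang::abort("gray image and ground-truth domain dimensions differ")
  }
  if (length(btv_values) == 0) rlang::abort("btv_values must be non-empty")
  btv_values <- as.integer(btv_values)
  if (is.unsorted(btv_values, strictly = TRUE)) {
    rlang::abort("btv_values must be strictly increasing")
  }
  gt_est <- run_replicates(gt, config)
  if (gt_est$D <= 0) {
    rlang::abort("ground-truth diffusivity is zero; d_ratio undefined")
  }
  res <- purrr::map_dbl(btv_values, function(b) {
    dom <- binarize(gray, b, cell_below_threshold)
    if (!any(dom$pore)) return(0)
    run_replicates(dom, config)$D
  })
  out <- tibble::tibble(btv = btv_values, D_cm2_s = res,
                        d_ratio = res / gt_est$D)
  attr(out, "d_gt") <- gt_est$D
  attr(out, "d_gt_relative") <- gt_est$D_relative
  attr(out, "optimal_btv") <- interp_crossing(as.numeric(btv_values),
                                              out$d_ratio, 1)
  class(out) <- c("btv_sweep", class(out))
  out
}

#' Pool heatmaps into a porosity-diffusivity table
#'
#' Concatenates per-subdomain (porosity, relative diffusivity) pairs across
#' one or more heatmaps, sorted by porosity — the raw material of the
#' porosity-diffusivity collapse plot, where local diffusivities from
#' sparse and dense regions fall on a common curve against local porosity.
#'
#' @param heatmaps A `diffusion_heatmap` or list of them.
#' @return A tibble with columns `porosity`, `d_relative` (one row per
#'   subdomain, no aggregation beyond concatenation), sorted by porosity.
#' @export
porosity_diffusivity_table <- function(heatmaps) {
  if (inherits(heatmaps, "diffusion_heatmap")) heatmaps <- list(heatmaps)
  if (length(heatmaps) == 0) rlang::abort("need at least one heatmap")
  stopifnot(all(purrr::map_lgl(heatmaps, inherits, "diffusion_heatmap")))
  purrr::map_dfr(heatmaps, function(h) {
    dplyr::select(h$subdomains, porosity, d_relative)
  }) |>
    dplyr::arrange(porosity)
}
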