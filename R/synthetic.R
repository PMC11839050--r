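# Seeded synthetic platelet-mass domains: random ellipse packings with a
# target porosity, instance-labelled ground-truth masks, pseudo-segmentation
# grayscale maps, and deterministic canonical geometries used as engine
# oracles.

#' Generate a synthetic ellipse-packing domain with ground truth
#'
#' Sequentially places randomly oriented, randomly sized ellipses
#' (idealised platelets) into an empty raster, rejecting any candidate
#' whose footprint — dilated by `min_gap_px` — would touch an existing
#' particle, until the rasterised porosity reaches
#' `target_porosity + 0.02`. When candidates are repeatedly rejected the
#' proposal radius is annealed downwards so that small particles fill the
#' remaining gaps, which lets packings span the sparse (~0.33) through
#' dense (~0.11) porosity regimes seen in platelet masses. Deterministic
#' for a fixed seed.
#'
#' @param extent_um Domain edge lengths in micrometres, length-2 (rows,
#'   cols); default `c(10, 10)`, the standard analysis tile.
#' @param pixel_size_nm Raster resolution (default 8 nm/px).
#' @param target_porosity Pore fraction aimed for, in `(0, 1)`.
#' @param mean_radius_um Mean equivalent ellipse radius (default 0.5 µm,
#'   platelet scale).
#' @param radius_cv Coefficient of variation of the lognormal radius
#'   distribution (default 0.35).
#' @param aspect_ratio_range Range of ellipse aspect ratios, sampled
#'   uniformly (default `c(1.2, 3)`; platelets in section are elongated).
#' @param min_gap_px Minimum pore gap, in pixels, preserved between
#'   neighbouring ellipses. The default 0 lets particles touch (but never
#'   overlap), matching the contact-dominated packing of dense platelet
#'   masses; a positive gap guarantees a connected inter-particle pore
#'   network.
#' @param seed RNG seed.
#' @param max_attempts Candidate budget before giving up (default 2e5;
#'   individual attempts are cheap).
#' @return A list with elements `domain` ([binary_domain()]) and `mask`
#'   ([label_mask()] with one label per placed ellipse), plus
#'   `achieved_porosity` and `n_ellipses`.
#' @examples
#' pk <- generate_packing(extent_um = c(1, 1), target_porosity = 0.5,
#'                        mean_radius_um = 0.12, seed = 1)
#' porosity(pk$domain)
#' @export
generate_packing <- function(extent_um = c(10, 10), pixel_size_nm = 8,
                             target_porosity = 0.33, mean_radius_um = 0.5,
                             radius_cv = 0.35,
                             aspect_ratio_range = c(1.2, 3),
                             min_gap_px = 0, seed = 1,
                             max_attempts = 200000) {
  if (length(extent_um) == 1) extent_um <- rep(extent_um, 2)
  if (target_porosity <= 0 || target_porosity >= 1) {
    rlang::abort("target_porosity must lie in (0, 1)")
  }
  if (mean_radius_um <= 0) rlang::abort("mean_radius_um must be positive")
  if (min_gap_px < 0) rlang::abort("min_gap_px must be >= 0")
  H <- round(extent_um[1] * 1000 / pixel_size_nm)
  W <- round(extent_um[2] * 1000 / pixel_size_nm)
  if (H < 8 || W < 8) rlang::abort("domain too small to pack")
  mean_r_px <- mean_radius_um * 1000 / pixel_size_nm

  # lognormal radius parameters from mean and CV
  sdlog <- sqrt(log(1 + radius_cv^2))
  meanlog <- log(mean_r_px) - sdlog^2 / 2

  withr::with_seed(seed, {
    labels <- matrix(0L, H, W)
    occupied <- matrix(FALSE, H, W)
    target_cell <- 1 - (target_porosity + 0.02)
    n_cell <- 0L
    n_placed <- 0L
    shrink <- 1
    fails <- 0L
    attempt <- 0L
    since_success <- 0L
    while (n_cell < target_cell * H * W && attempt < max_attempts) {
      attempt <- attempt + 1L
      since_success <- since_success + 1L
      if (since_success > 4000L) break  # jammed: no pocket admits the minimum size
      r <- stats::rlnorm(1, meanlog, sdlog) * shrink
      r <- max(r, 1.3)
      asp <- stats::runif(1, aspect_ratio_range[1], aspect_ratio_range[2])
      # the smallest fill-in particles (platelet fragments) are near-round;
      # elongated shapes below a few pixels rasterise to slivers
      if (r < 4) asp <- 1 + (asp - 1) * r / 4
      a <- r * sqrt(asp)
      b <- r / sqrt(asp)
      theta <- stats::runif(1, 0, pi)
      # centre drawn uniformly over still-free pixels (cheap retry loop),
      # so late candidates land in the remaining pore pockets
      cy <- NA
      for (k in 1:200) {
        iy <- sample.int(H, 1L); ix <- sample.int(W, 1L)
        if (!occupied[iy, ix]) {
          cy <- iy + stats::runif(1, -0.5, 0.5)
          cx <- ix + stats::runif(1, -0.5, 0.5)
          break
        }
      }
      if (is.na(cy)) next
      # candidate footprint dilated by the gap; reject on any contact
      guard <- ellipse_pixels(cy, cx, a + min_gap_px, b + min_gap_px, theta,
                              H, W)
      if (length(guard) == 0 || any(occupied[guard])) {
        fails <- fails + 1L
        if (fails >= 15L) {  # anneal the proposal size towards the pocket scale
          shrink <- shrink * 0.92
          fails <- 0L
        }
        next
      }
      body <- ellipse_pixels(cy, cx, a, b, theta, H, W)
      if (length(body) == 0) next
      n_placed <- n_placed + 1L
      labels[body] <- n_placed
      occupied[body] <- TRUE
      n_cell <- n_cell + length(body)
      fails <- 0L
      since_success <- 0L
    }
    achieved <- 1 - n_cell / (H * W)
    if (achieved > target_porosity + 0.05) {
      rlang::abort(sprintf(
        "packing stalled at porosity %.3f (target %.3f) after %d attempts; relax shape parameters",
        achieved, target_porosity, attempt))
    }
    list(domain = binary_domain(labels == 0L, spacing_nm = pixel_size_nm),
         mask = label_mask(labels, pixel_size_nm = pixel_size_nm),
         achieved_porosity = achieved,
         n_ellipses = n_placed)
  })
}

# linear (column-major) indices of raster pixels inside an ellipse,
# clipped to an H x W grid; pixel centers at integer coordinates (1-based)
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  rmax <- max(a, b)
  i0 <- max(1L, floor(cy - rmax)); i1 <- min(H, ceiling(cy + rmax))
  j0 <- max(1L, floor(cx - rmax)); j1 <- min(W, ceiling(cx + rmax))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  dy <- ii - cy
  dx <- rep(jj - cx, each = length(ii))
  dyr <- rep(dy, times = length(jj))
  u <- (dx * cos(theta) + dyr * sin(theta)) / a
  v <- (-dx * sin(theta) + dyr * cos(theta)) / b
  inside <- u * u + v * v <= 1
  rows <- rep(ii, times = length(jj))[inside]
  cols <- rep(jj, each = length(ii))[inside]
  (cols - 1L) * H + rows
}

#' Render a pseudo-segmentation grayscale map from a domain
#'
#' Emulates the rendered output of a segmentation network: the domain is
#' painted cell = 0, pore = 255, Gaussian-blurred to soften boundaries
#' (as probability/flow maps are), then perturbed with clipped additive
#' Gaussian noise. With zero blur and zero noise, binarizing at any
#' threshold in `(0, 255]` with the default polarity reproduces the input
#' domain exactly.
#'
#' @param domain A [binary_domain()].
#' @param blur_sigma_px Gaussian blur standard deviation in pixels (>= 0).
#' @param noise_sd Additive Gaussian noise SD in brightness units (>= 0).
#' @param seed RNG seed for the noise.
#' @return A [gray_image()] at the domain's spacing.
#' @examples
#' dom <- generate_canonical("checkerboard", dim = c(16, 16))
#' g <- render_pseudo_map(dom, blur_sigma_px = 0, noise_sd = 0)
#' iou(binarize(g, 128), dom)
#' @export
render_pseudo_map <- function(domain, blur_sigma_px = 2, noise_sd = 10,
                              seed = 1) {
  stopifnot(inherits(domain, "binary_domain"))
  if (blur_sigma_px < 0 || noise_sd < 0) {
    rlang::abort("blur_sigma_px and noise_sd must be >= 0")
  }
  base <- ifelse(domain$pore, 255, 0)
  if (blur_sigma_px > 0) {
    base <- EBImage::gblur(base / 255, sigma = blur_sigma_px,
                           boundary = "replicate") * 255
  }
  if (noise_sd > 0) {
    base <- base + withr::with_seed(seed,
      stats::rnorm(length(base), sd = noise_sd))
  }
  px <- pmin(pmax(round_half_up(base), 0), 255)
  gray_image(matrix(as.integer(px), nrow(domain$pore), ncol(domain$pore)),
             pixel_size_nm = domain$spacing_nm)
}

#' Deterministic canonical domains
#'
#' Named oracle geometries with closed-form or easily reasoned transport
#' behaviour, used to validate the diffusion engine:
#' \describe{
#'   \item{`empty`}{all pore — free diffusion, \eqn{D = D_p}.}
#'   \item{`full`}{all cell — invalid for simulation, exercises error
#'     contracts.}
#'   \item{`single_pore`}{one pore site at the centre of a cell field —
#'     fully caged, \eqn{MSD \equiv 0}.}
#'   \item{`channel`}{a straight pore channel of `width` rows spanning the
#'     domain; at `width = 1` the walk is one-dimensional and
#'     \eqn{D = D_p/2}.}
#'   \item{`checkerboard`}{alternating pore/cell, porosity exactly 1/2.}
#'   \item{`walled_box`}{pore interior enclosed by a 1-pixel cell wall.}
#' }
#'
#' @param name One of the geometry names above.
#' @param dim Length-2 integer dimensions (rows, cols).
#' @param spacing_nm Lattice spacing (default 8 nm).
#' @param width Channel width in rows (channel geometry only).
#' @return A [binary_domain()].
#' @examples
#' porosity(generate_canonical("channel", dim = c(9, 50), width = 1))
#' @export
generate_canonical <- function(name, dim = c(64, 64), spacing_nm = 8,
                               width = 1) {
  if (length(dim) == 1) dim <- rep(dim, 2)
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  if (H < 1 || W < 1) rlang::abort("dimensions must be positive")
  pore <- switch(
    name,
    empty = matrix(TRUE, H, W),
    full = matrix(FALSE, H, W),
    single_pore = {
      m <- matrix(FALSE, H, W)
      m[(H + 1L) %/% 2L, (W + 1L) %/% 2L] <- TRUE
      m
    },
    channel = {
      if (width < 1 || width > H) rlang::abort("invalid channel width")
      m <- matrix(FALSE, H, W)
      r0 <- (H - width) %/% 2L + 1L
      m[r0:(r0 + width - 1L), ] <- TRUE
      m
    },
    checkerboard = outer(seq_len(H), seq_len(W), function(i, j) (i + j) %% 2 == 0),
    walled_box = {
      if (H < 3 || W < 3) rlang::abort("walled_box needs dimensions >= 3")
      m <- matrix(FALSE, H, W)
      m[2:(H - 1L), 2:(W - 1L)] <- TRUE
      m
    },
    rlang::abort(sprintf("unknown canonical geometry '%s'", name))
  )
  binary_domain(pore, spacing_nm = spacing_nm)
}
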