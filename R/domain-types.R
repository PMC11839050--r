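#' Grayscale segmentation image
#'
#' Light container for an 8-bit grayscale raster at a known physical pixel
#' size. This is the form in which segmentation-network outputs (cell
#' probability or gradient-flow maps rendered as images) enter the pipeline
#' before binarization.
#'
#' @param pixels Integer matrix of brightness values in `[0, 255]`
#'   (rows = y, columns = x).
#' @param pixel_size_nm Physical edge length of one pixel in nanometres
#'   (default 8, the serial block-face SEM resolution the pipeline targets).
#' @return An object of class `gray_image` with fields `pixels` and
#'   `pixel_size_nm`.
#' @examples
#' img <- gray_image(matrix(0:249, 25, 10), pixel_size_nm = 8)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, pixel_size_nm = 8) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    rlang::abort("gray_image must have both dimensions >= 1")
  }
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L)) {
    rlang::abort("gray_image brightness values must lie in [0, 255]")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    rlang::abort("pixel_size_nm must be a single positive number")
  }
  structure(list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "gray_image")
}

#' Binary pore/cell lattice domain
#'
#' The computational domain for lattice kinetic Monte Carlo diffusion: every
#' lattice site is either `pore` (accessible to tracers) or `cell`
#' (inaccessible), at a fixed lattice spacing.
#'
#' @param pore Logical matrix; `TRUE` marks a pore site, `FALSE` a cell site.
#' @param spacing_nm Lattice spacing h in nanometres (default 8).
#' @return An object of class `binary_domain` with fields `pore` (logical
#'   matrix) and `spacing_nm`.
#' @examples
#' dom <- binary_domain(matrix(TRUE, 4, 4))
#' porosity(dom)
#' @export
binary_domain <- function(pore, spacing_nm = 8) {
  pore <- as.matrix(pore)
  if (!is.logical(pore)) {
    rlang::abort("`pore` must be a logical matrix (TRUE = pore, FALSE = cell)")
  }
  if (anyNA(pore)) rlang::abort("`pore` must not contain NA: every site is exactly one of pore/cell")
  if (nrow(pore) < 1 || ncol(pore) < 1) {
    rlang::abort("binary_domain must have both dimensions >= 1")
  }
  if (!is.numeric(spacing_nm) || length(spacing_nm) != 1 || spacing_nm <= 0) {
    rlang::abort("spacing_nm must be a single positive number")
  }
  structure(list(pore = pore, spacing_nm = as.numeric(spacing_nm)),
            class = "binary_domain")
}

#' Instance-labelled ground-truth mask
#'
#' Manual annotations: label 0 is background/pore, label k > 0 is cell
#' instance k. Binarization of such a mask is label-agnostic
#' (see [mask_to_domain()]).
#'
#' @param labels Non-negative integer matrix of instance labels.
#' @param pixel_size_nm Physical pixel size in nanometres (default 8).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_nm = 8) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) < 1 || ncol(labels) < 1) {
    rlang::abort("label_mask must have both dimensions >= 1")
  }
  if (anyNA(labels) || any(labels < 0L)) {
    rlang::abort("labels must be non-negative integers")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    rlang::abort("pixel_size_nm must be a single positive number")
  }
  structure(list(labels = labels, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "label_mask")
}

#' Porosity of a binary domain
#'
#' Fraction of lattice sites classified as pore, i.e. accessible to
#' diffusing tracers.
#'
#' @param domain A [binary_domain()].
#' @return A number in `[0, 1]`.
#' @examples
#' porosity(generate_canonical("checkerboard", dim = c(4, 4)))
#' @export
porosity <- function(domain) {
  stopifnot(inherits(domain, "binary_domain"))
  mean(domain$pore)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px @ %g nm/px, brightness [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_domain <- function(x, ...) {
  cat(sprintf("<binary_domain> %d x %d sites @ %g nm, porosity %.3f\n",
              nrow(x$pore), ncol(x$pore), x$spacing_nm, porosity(x)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px @ %g nm/px, %d instances\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_nm,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
dim.binary_domain <- function(x) dim(x$pore)

#' @export
dim.label_mask <- function(x) dim(x$labels)

# physical extent helper, in micrometres
domain_extent_um <- function(domain) {
  dim(domain$pore) * domain$spacing_nm / 1000
}
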