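# Raster reading/writing, grayscale conversion, binarization and IoU.
# PNG and TIFF are handled by the png and tiff packages; these wrappers add
# 8-bit validation, NTSC luma, and the cell/pore conventions used downstream.

round_half_up <- function(x) floor(x + 0.5)

#' Read an 8-bit raster image
#'
#' Reads a PNG or TIFF segmentation-output image and returns it as an
#' integer array scaled to `[0, 255]`, with 1 (grayscale) or 3 (RGB)
#' channels. 16-bit rasters are rejected: the binarization contract is
#' defined on 8-bit brightness (use [read_label_mask()] for 16-bit
#' ground-truth masks).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix (grayscale) or H x W x 3 integer array (RGB),
#'   values in `[0, 255]`.
#' @seealso [to_grayscale()], [read_label_mask()]
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("raster file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
  } else {
    rlang::abort(sprintf("unsupported raster format '%s' for '%s' (PNG/TIFF only)",
                         ext, path))
  }
  if (!is.null(depth) && !all(depth == 8)) {
    rlang::abort(sprintf("unsupported bit depth %s in '%s': 8-bit rasters only",
                         paste(unique(depth), collapse = "/"), path))
  }
  img <- unclass(img)
  attributes(img) <- list(dim = dim(img))
  nch <- if (length(dim(img)) == 2) 1L else dim(img)[3]
  if (!nch %in% c(1L, 3L, 4L)) {
    rlang::abort(sprintf("unsupported channel count %d in '%s'", nch, path))
  }
  if (nch == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  out <- round_half_up(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Convert a raster to grayscale via the NTSC luma formula
#'
#' RGB brightness is collapsed to `0.299 R + 0.587 G + 0.114 B`, rounded
#' half-up to an integer in `[0, 255]`. Single-channel input passes through
#' unchanged.
#'
#' @param image Integer matrix or H x W x 3 array with values in `[0, 255]`
#'   (e.g. from [read_raster()]), or an existing [gray_image()].
#' @param pixel_size_nm Physical pixel size in nanometres (default 8).
#' @return A [gray_image()].
#' @examples
#' rgb <- array(c(255, 0, 100), dim = c(1, 1, 3))
#' to_grayscale(rgb)$pixels  # 0.299*255 + 0.587*0 + 0.114*100
#' @export
to_grayscale <- function(image, pixel_size_nm = 8) {
  if (inherits(image, "gray_image")) return(image)
  d <- dim(image)
  if (length(d) == 2) {
    return(gray_image(image, pixel_size_nm))
  }
  if (length(d) == 3 && d[3] == 3) {
    luma <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    return(gray_image(round_half_up(luma), pixel_size_nm))
  }
  rlang::abort("image must have 1 or 3 channels (8-bit grayscale or RGB)")
}

#' Binarize a grayscale image into a pore/cell domain
#'
#' Applies a brightness threshold value (BTV): with the default polarity,
#' every pixel with brightness strictly lower than the BTV becomes a `cell`
#' site, all others `pore`. Equality at the threshold maps to pore
#' ("lower than" is strict). `cell_below_threshold = FALSE` inverts the rule
#' for maps whose cells render bright.
#'
#' @param gray A [gray_image()].
#' @param btv Integer brightness threshold in `[0, 256]`.
#' @param cell_below_threshold Polarity flag (default `TRUE`).
#' @return A [binary_domain()] with `spacing_nm` equal to the image's
#'   `pixel_size_nm` and the same dimensions.
#' @examples
#' g <- gray_image(matrix(c(5L, 11L, 200L, 12L), 2, 2))
#' binarize(g, btv = 12)$pore  # cell iff brightness < 12
#' @export
binarize <- function(gray, btv, cell_below_threshold = TRUE) {
  stopifnot(inherits(gray, "gray_image"))
  if (!is.numeric(btv) || length(btv) != 1 || btv != round(btv) ||
      btv < 0 || btv > 256) {
    rlang::abort("btv must be a single integer in [0, 256]")
  }
  cell <- gray$pixels < btv
  if (!cell_below_threshold) cell <- !cell
  binary_domain(!cell, spacing_nm = gray$pixel_size_nm)
}

#' Collapse an instance-labelled mask to a binary domain
#'
#' Any positive label becomes `cell`; label 0 becomes `pore`. Instance
#' identity is discarded — manually labelled images are effectively already
#' binarized, and serve as the ground truth for both IoU and functional
#' (diffusivity-based) comparisons.
#'
#' @param mask A [label_mask()].
#' @return A [binary_domain()].
#' @export
mask_to_domain <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  binary_domain(mask$labels == 0L, spacing_nm = mask$pixel_size_nm)
}

#' Pixelwise intersection-over-union of two binary domains
#'
#' For each pixel the intersection counts 1 if both domains mark it `cell`,
#' and the union counts 1 if either does; IoU is their ratio. When neither
#' domain contains any cell pixel the union is empty and the score is
#' defined as 1 (two all-pore masks agree perfectly).
#'
#' @param a,b [binary_domain()] objects of identical dimensions.
#' @return A number in `[0, 1]`.
#' @examples
#' a <- binary_domain(matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
#' iou(a, a)
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "binary_domain"), inherits(b, "binary_domain"))
  if (!identical(dim(a$pore), dim(b$pore))) {
    rlang::abort("iou: domains must have identical dimensions")
  }
  cell_a <- !a$pore
  cell_b <- !b$pore
  union_n <- sum(cell_a | cell_b)
  if (union_n == 0) return(1)
  sum(cell_a & cell_b) / union_n
}

#' Write / read a binary domain as PNG plus JSON sidecar
#'
#' Domains round-trip losslessly as 8-bit grayscale PNG with cell = 0 and
#' pore = 255; the lattice spacing is stored in a JSON sidecar
#' `<path>.json` as `{"spacing_nm": <number>}`.
#'
#' @param domain A [binary_domain()].
#' @param path Output `.png` path.
#' @return `write_domain()` returns `path` invisibly; `read_domain()`
#'   returns a [binary_domain()].
#' @export
write_domain <- function(domain, path) {
  stopifnot(inherits(domain, "binary_domain"))
  png::writePNG(ifelse(domain$pore, 1, 0), path)
  jsonlite::write_json(list(spacing_nm = domain$spacing_nm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain
#' @export
read_domain <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 3) img <- to_grayscale(img)$pixels
  sidecar <- paste0(path, ".json")
  spacing <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$spacing_nm
  } else {
    8
  }
  binary_domain(img >= 128L, spacing_nm = spacing)
}

#' Write / read an instance label mask
#'
#' Masks are written as 16-bit single-channel TIFF so that up to 65535 cell
#' instances survive the round trip; `read_label_mask()` also accepts 16-bit
#' or 8-bit PNG. Pixel size travels in a JSON sidecar like domains do.
#'
#' @param mask A [label_mask()].
#' @param path Output `.tif` path.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) rlang::abort("labels exceed 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_nm = mask$pixel_size_nm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("label mask file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
  } else {
    rlang::abort(sprintf("unsupported mask format '%s' for '%s'", ext, path))
  }
  if (length(dim(img)) == 3) {
    rlang::abort(sprintf("label mask '%s' must be single-channel", path))
  }
  img <- unclass(img)
  attributes(img) <- list(dim = dim(img))
  scale <- if (!is.null(depth) && all(depth == 16)) 65535 else 255
  labels <- round_half_up(img * scale)
  sidecar <- paste0(path, ".json")
  px <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$pixel_size_nm
  } else {
    8
  }
  label_mask(labels, pixel_size_nm = px)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param gray A [gray_image()].
#' @param path Output `.png` path.
#' @export
write_raster <- function(gray, path) {
  stopifnot(inherits(gray, "gray_image"))
  png::writePNG(gray$pixels / 255, path)
  invisible(path)
}

#' Coarsen a binary domain by an integer factor
#'
#' Block-aggregates `factor` x `factor` groups of sites; a coarse site is
#' pore only if every constituent fine site is pore (conservative
#' excluded-volume rule, so porosity never increases under coarsening).
#' The lattice spacing scales by `factor`, emulating a larger effective
#' tracer on the same microstructure.
#'
#' @param domain A [binary_domain()].
#' @param factor Positive integer that divides both domain dimensions.
#' @return A coarser [binary_domain()].
#' @examples
#' cb <- generate_canonical("checkerboard", dim = c(4, 4))
#' porosity(resample_domain(cb, 2))  # every 2x2 block contains a cell
#' @export
resample_domain <- function(domain, factor) {
  stopifnot(inherits(domain, "binary_domain"))
  if (!is.numeric(factor) || length(factor) != 1 || factor != round(factor) ||
      factor < 1) {
    rlang::abort("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  d <- dim(domain$pore)
  if (any(d %% factor != 0)) {
    rlang::abort(sprintf(
      "factor %d does not divide domain dimensions %d x %d", factor, d[1], d[2]))
  }
  if (factor == 1L) return(domain)
  blocks <- array(domain$pore, c(factor, d[1] %/% factor, factor, d[2] %/% factor))
  coarse <- apply(blocks, c(2, 4), all)
  binary_domain(coarse, spacing_nm = domain$spacing_nm * factor)
}
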