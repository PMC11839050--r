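# Grayscale conversion, binarization, masks, IoU, raster round trips,
# and block resampling.

test_that("NTSC luma collapses RGB to grayscale with half-up rounding", {
  px <- function(r, g, b) {
    img <- array(c(r, g, b), dim = c(1, 1, 3))
    to_grayscale(img)$pixels[1, 1]
  }
  expect_identical(px(255, 255, 255), 255L)
  expect_identical(px(0, 0, 0), 0L)
  expect_identical(px(100, 100, 100), 100L)  # weights sum to 1
  # mixed channel: fixed-point luma computed directly from the weights
  expect_identical(px(255, 0, 100), as.integer(floor(0.299 * 255 + 0.114 * 100 + 0.5)))
  expect_identical(px(10, 20, 30), as.integer(floor(0.299 * 10 + 0.587 * 20 + 0.114 * 30 + 0.5)))
  # single-channel passes through unchanged
  m <- matrix(c(0L, 17L, 128L, 255L), 2, 2)
  expect_identical(to_grayscale(m)$pixels, m)
  # channel-count contract
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))), "channel")
})

test_that("binarization uses the strict lower-than rule with polarity flag", {
  g <- gray_image(matrix(c(5L, 11L, 200L, 12L), 2, 2))
  dom <- binarize(g, btv = 12)
  # cell iff brightness < 12; 12 itself is not lower than 12
  expect_identical(dom$pore, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(dom$spacing_nm, g$pixel_size_nm)
  # inverted polarity flips every site
  inv <- binarize(g, btv = 12, cell_below_threshold = FALSE)
  expect_identical(inv$pore, !dom$pore)

  bright <- gray_image(matrix(255L, 3, 3))
  expect_equal(porosity(binarize(bright, 12)), 1)     # nothing below 12
  expect_equal(porosity(binarize(random_gray(), 0)), 1)    # brightness < 0 impossible
  expect_equal(porosity(binarize(random_gray(), 256)), 0)  # everything below 256
  expect_error(binarize(g, 257), "btv")
  expect_error(binarize(g, 12.5), "btv")
})

test_that("cell-pixel count is monotone in the threshold", {
  g <- random_gray(30, 30, seed = 9)
  btvs <- seq(0, 256, by = 16)
  cells <- vapply(btvs, function(b) sum(!binarize(g, b)$pore), numeric(1))
  expect_true(all(diff(cells) >= 0))
  cells_inv <- vapply(btvs, function(b) {
    sum(!binarize(g, b, cell_below_threshold = FALSE)$pore)
  }, numeric(1))
  expect_true(all(diff(cells_inv) <= 0))
})

test_that("label masks collapse to binary domains label-agnostically", {
  expect_equal(porosity(mask_to_domain(label_mask(matrix(0L, 4, 4)))), 1)
  m <- matrix(0L, 5, 5)
  m[2:3, 2:4] <- 1L
  dom <- mask_to_domain(label_mask(m))
  expect_identical(!dom$pore, m > 0L)
  # touching instances 1 and 2 both become cell; identity is discarded
  m2 <- m
  m2[2:3, 4] <- 2L
  expect_identical(mask_to_domain(label_mask(m2))$pore,
                   mask_to_domain(label_mask(m))$pore)
})

test_that("IoU counts shared cell pixels over the union", {
  base <- matrix(TRUE, 10, 20)
  a <- base; a[1:5, 1:20] <- FALSE            # 100 cell pixels
  b <- base; b[1:5, 1:10] <- FALSE            # 50 of them, none extra
  expect_equal(iou(binary_domain(a), binary_domain(b)), 0.5)
  expect_equal(iou(binary_domain(a), binary_domain(a)), 1)
  disj <- base; disj[6:10, 1:20] <- FALSE
  expect_equal(iou(binary_domain(a), binary_domain(disj)), 0)
  # empty-union convention: two all-pore masks agree perfectly
  expect_equal(iou(binary_domain(base), binary_domain(base)), 1)
  expect_error(iou(binary_domain(base), binary_domain(matrix(TRUE, 5, 5))),
               "dimensions")
})

test_that("IoU is symmetric and bounded on random mask pairs", {
  withr::with_seed(11, {
    for (k in 1:20) {
      a <- binary_domain(matrix(sample(c(TRUE, FALSE), 64, replace = TRUE), 8, 8))
      b <- binary_domain(matrix(sample(c(TRUE, FALSE), 64, replace = TRUE), 8, 8))
      s <- iou(a, b)
      expect_identical(s, iou(b, a))
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  })
})

test_that("domains round-trip losslessly through PNG plus sidecar", {
  dom <- small_packing(0.4, px = 48, seed = 3)$domain
  path <- withr::local_tempfile(fileext = ".png")
  write_domain(dom, path)
  expect_true(file.exists(paste0(path, ".json")))
  expect_same_domain(read_domain(path), dom)
})

test_that("raster readers enforce the 8-bit contract and name paths", {
  expect_error(read_raster("no/such/file.png"), "no/such/file.png")
  bmp <- withr::local_tempfile(fileext = ".bmp")
  writeLines("not an image", bmp)
  expect_error(read_raster(bmp), "format")
  # 16-bit TIFF is rejected with the offending depth and file named
  deep <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), deep, bits.per.sample = 16L)
  expect_error(read_raster(deep), "16")
  # 3-channel PNG is accepted and converts downstream
  rgbf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(27), dim = c(3, 3, 3)), rgbf)
  img <- read_raster(rgbf)
  expect_equal(dim(img), c(3, 3, 3))
  expect_s3_class(to_grayscale(img), "gray_image")
})

test_that("label masks round-trip 16-bit with instance counts above 255", {
  withr::with_seed(5, {
    labels <- matrix(sample(0:300, 400, replace = TRUE), 20, 20)
  })
  mask <- label_mask(labels, pixel_size_nm = 16)
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(mask, path)
  back <- read_label_mask(path)
  expect_identical(back$labels, mask$labels)
  expect_equal(back$pixel_size_nm, 16)
})

test_that("resampling is conservative block aggregation", {
  allp <- generate_canonical("empty", dim = c(4, 4))
  coarse <- resample_domain(allp, 2)
  expect_equal(dim(coarse$pore), c(2, 2))
  expect_equal(porosity(coarse), 1)
  expect_equal(coarse$spacing_nm, 2 * allp$spacing_nm)
  # one cell pixel poisons its 2x2 block
  m <- matrix(TRUE, 4, 4); m[1, 2] <- FALSE
  expect_identical(resample_domain(binary_domain(m), 2)$pore,
                   matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  # checkerboard: every block contains a cell pixel
  cb <- generate_canonical("checkerboard", dim = c(4, 4))
  expect_equal(porosity(resample_domain(cb, 2)), 0)
  expect_error(resample_domain(allp, 3), "divide")
})

test_that("porosity never increases under coarsening", {
  withr::with_seed(21, {
    for (k in 1:10) {
      dom <- binary_domain(matrix(stats::runif(144) > 0.4, 12, 12))
      expect_lte(porosity(resample_domain(dom, 2)), porosity(dom))
      expect_lte(porosity(resample_domain(dom, 3)), porosity(dom))
    }
  })
})
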