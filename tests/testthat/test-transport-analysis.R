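# Subdomain tiling combinatorics, overlap-averaged heatmaps, the BTV
# calibration sweep, and porosity-diffusivity aggregation.

test_that("staggered tiling yields the documented origin counts", {
  # 10 x 10 um^2 at 8 nm/px, 2 um window, 1 um stride -> 9 x 9 = 81
  big <- binary_domain(matrix(TRUE, 1250, 1250), spacing_nm = 8)
  tiles <- tile_subdomains(big, window_um = 2, stride_um = 1)
  expect_equal(nrow(tiles), 81)
  expect_equal(attr(tiles, "window_px"), 250)
  expect_equal(attr(tiles, "stride_px"), 125)
  # row-major origins on the stride grid
  expect_equal(tiles$row_px[1:10], c(rep(0L, 9), 125L))
  # exact fit -> single origin; 500 px -> 3 positions per axis
  exact <- binary_domain(matrix(TRUE, 250, 250), spacing_nm = 8)
  expect_equal(nrow(tile_subdomains(exact, 2, 1)), 1)
  mid <- binary_domain(matrix(TRUE, 500, 500), spacing_nm = 8)
  expect_equal(nrow(tile_subdomains(mid, 2, 1)), 9)
  # contracts
  expect_error(tile_subdomains(exact, 3, 1), "exceeds")
  expect_error(tile_subdomains(exact, 0.5004, 1), "whole number")
})

test_that("subdomain porosities bracket the whole-domain porosity", {
  pk <- small_packing(0.35, px = 96, seed = 12)
  tiles <- tile_subdomains(pk$domain, window_um = 0.256, stride_um = 0.128)
  expect_gte(porosity(pk$domain), min(tiles$porosity))
  expect_lte(porosity(pk$domain), max(tiles$porosity))
})

test_that("overlap averaging follows the 1/2/4-fold containment rule", {
  pk <- small_packing(0.4, px = 128, seed = 9)
  cfg <- fast_config(n_particles = 40, replicates = 1, t_end = 2e-4,
                     t_fit_start = 5e-5)
  hm <- diffusion_heatmap(pk$domain, cfg, window_um = 0.256,
                          stride_um = 0.128)
  # 128 px / 16-px stride -> 8x8 = 64 unit cells from 7x7 = 49 subdomains
  expect_equal(nrow(hm$subdomains), 49)
  expect_equal(hm$n_cells, c(8, 8))
  cnt <- hm$overlap_count
  expect_equal(cnt[1, 1], 1L)                      # corner
  expect_equal(cnt[1, 4], 2L)                      # edge
  expect_true(all(cnt[2:7, 2:7] == 4L))            # interior
  # every unit-cell value is a mean of its contributing subdomain values
  expect_true(all(hm$local_d >= min(hm$subdomains$d_relative) - 1e-12))
  expect_true(all(hm$local_d <= max(hm$subdomains$d_relative) + 1e-12))
  expect_true(all(hm$local_porosity >= min(hm$subdomains$porosity) - 1e-12))
  expect_true(all(hm$local_porosity <= max(hm$subdomains$porosity) + 1e-12))
  # an interior cell averages exactly the 4 windows that contain it
  sub <- hm$subdomains
  stride <- 16; w_cells <- 2
  cell <- c(3L, 5L)  # 0-based unit-cell index, interior
  holders <- sub[(sub$row_px / stride) %in% ((cell[1] - w_cells + 1):cell[1]) &
                 (sub$col_px / stride) %in% ((cell[2] - w_cells + 1):cell[2]), ]
  expect_equal(nrow(holders), 4)
  expect_equal(hm$local_d[cell[1] + 1, cell[2] + 1], mean(holders$d_relative))
  # the porosity grid is exact (no Monte Carlo), so check it numerically too
  expect_equal(hm$local_porosity[cell[1] + 1, cell[2] + 1],
               mean(holders$porosity))
})

test_that("heatmap of an open domain is uniformly free-diffusive", {
  dom <- binary_domain(matrix(TRUE, 96, 96), spacing_nm = 8)
  cfg <- fast_config(n_particles = 150, replicates = 2)
  hm <- diffusion_heatmap(dom, cfg, window_um = 0.256, stride_um = 0.128)
  expect_true(all(hm$local_porosity == 1))
  expect_equal(unname(as.vector(hm$local_d)),
               rep(1, length(hm$local_d)), tolerance = 0.15)
})

test_that("unity crossing is interpolated between bracketing sweep points", {
  ic <- porewalk:::interp_crossing
  expect_equal(ic(c(10, 20), c(0.8, 1.2)), 15)     # linear interpolation
  expect_equal(ic(c(10, 20, 30), c(1.4, 1.2, 1.1)), NA_real_)  # no crossing
  expect_equal(ic(c(10, 20, 30), c(1.3, 1.0, 0.7)), 20)        # exact hit
  expect_equal(ic(c(0, 10, 20, 30), c(1.5, 0.5, 1.5, 0.5)), 5) # first crossing
  expect_equal(ic(c(5, 9), c(1.2, 0.8)), 7)
})

test_that("a faithful rendering calibrates to ratio exactly 1 at any threshold", {
  pk <- small_packing(0.4, px = 64, seed = 10)
  gray <- render_pseudo_map(pk$domain, blur_sigma_px = 0, noise_sd = 0)
  cfg <- fast_config(n_particles = 80, replicates = 2, t_end = 3e-4,
                     t_fit_start = 1e-4)
  sw <- btv_sweep(gray, pk$domain, btv_values = c(1, 50, 128, 255),
                  config = cfg)
  # binarization reproduces the ground truth exactly, and identical domains
  # under identical seeds give identical diffusivities
  expect_equal(sw$d_ratio, rep(1, 4))
  expect_error(btv_sweep(gray, generate_canonical("empty", dim = c(8, 8)),
                         config = cfg), "dimensions")
})

test_that("sweep on a blurred map brackets an optimum near unity ratio", {
  pk <- small_packing(0.35, px = 96, seed = 7)
  gray <- render_pseudo_map(pk$domain, blur_sigma_px = 2, noise_sd = 5,
                            seed = 2)
  cfg <- fast_config(n_particles = 150, replicates = 2, t_end = 5e-4,
                     t_fit_start = 2e-4, seed = 3)
  sw <- btv_sweep(gray, pk$domain, btv_values = seq(40, 220, by = 30),
                  config = cfg)
  opt <- attr(sw, "optimal_btv")
  expect_true(is.finite(opt))
  expect_gte(opt, 40); expect_lte(opt, 220)
  # re-simulating at the (rounded) optimum lands near the ground truth
  dom_opt <- binarize(gray, round(opt))
  est <- run_replicates(dom_opt, cfg)
  ratio <- est$D / attr(sw, "d_gt")
  expect_equal(ratio, 1, tolerance = 0.2)
})

test_that("porosity-diffusivity table pools and sorts subdomain pairs", {
  cfg <- fast_config(n_particles = 40, replicates = 1, t_end = 2e-4,
                     t_fit_start = 5e-5)
  hm1 <- diffusion_heatmap(small_packing(0.25, px = 64, seed = 1)$domain,
                           cfg, window_um = 0.256, stride_um = 0.256)
  hm2 <- diffusion_heatmap(small_packing(0.55, px = 64, seed = 2)$domain,
                           cfg, window_um = 0.256, stride_um = 0.256)
  tab <- porosity_diffusivity_table(list(hm1, hm2))
  expect_equal(nrow(tab), nrow(hm1$subdomains) + nrow(hm2$subdomains))
  expect_false(is.unsorted(tab$porosity))
  # denser packings sit lower on the curve
  expect_gt(mean(hm2$subdomains$d_relative), mean(hm1$subdomains$d_relative))
  single <- porosity_diffusivity_table(hm1)
  expect_equal(nrow(single), nrow(hm1$subdomains))
})

test_that("tidiers expose sweep, estimate and heatmap results as tibbles", {
  pk <- small_packing(0.4, px = 48, seed = 4)
  cfg <- fast_config(n_particles = 40, replicates = 2, t_end = 2e-4,
                     t_fit_start = 5e-5)
  est <- run_replicates(pk$domain, cfg)
  expect_s3_class(tidy(est), "tbl_df")
  expect_named(glance(est),
               c("D_cm2_s", "D_relative", "dispersion", "n_replicates",
                 "n_particles", "t_fit_start_s", "t_end_s"))
  hm <- diffusion_heatmap(pk$domain, cfg, window_um = 0.256,
                          stride_um = 0.128)
  td <- tidy(hm)
  expect_equal(nrow(td), prod(hm$n_cells))
  expect_equal(td$d_relative[td$row == 1 & td$col == 2],
               hm$local_d[2, 3])
  expect_equal(glance(hm)$n_cells, prod(hm$n_cells))
})
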