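# shared fixture builders; everything is generated in code

# short, cheap simulation settings for unit tests (acceptance tests use the
# full protocol)
fast_config <- function(n_particles = 200, replicates = 2, t_end = 5e-4,
                        t_fit_start = 2e-4, seed = 42, ...) {
  sim_config(n_particles = n_particles, replicates = replicates,
             t_end = t_end, t_fit_start = t_fit_start, seed = seed, ...)
}

# small seeded packing for obstacle tests
small_packing <- function(porosity = 0.33, px = 100, seed = 1) {
  generate_packing(extent_um = c(px * 8 / 1000, px * 8 / 1000),
                   target_porosity = porosity, mean_radius_um = 0.12,
                   seed = seed)
}

# deterministic pseudo-random gray image
random_gray <- function(h = 20, w = 20, seed = 1) {
  withr::with_seed(seed,
    gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w)))
}

expect_same_domain <- function(a, b) {
  expect_identical(a$pore, b$pore)
  expect_equal(a$spacing_nm, b$spacing_nm)
}
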