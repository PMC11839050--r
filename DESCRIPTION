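Package: porewalk
Title: Lattice Kinetic Monte Carlo Diffusion in Binarized Cellular Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts grayscale segmentation maps of densely packed cellular
    media (such as platelet masses imaged by serial block-face scanning
    electron microscopy) into binary pore/cell lattice domains, simulates
    hindered tracer diffusion on those domains with an event-driven lattice
    kinetic Monte Carlo engine (Next Reaction method with mirror boundary
    conditions), and estimates local diffusivities from mean squared
    displacement. Includes brightness-threshold calibration against
    ground-truth masks, staggered-subdomain diffusivity heatmaps,
    porosity-diffusivity aggregation, pixelwise intersection-over-union
    scoring, and a seeded synthetic ellipse-packing generator so the whole
    pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage,
    optparse,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
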