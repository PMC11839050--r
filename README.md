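# porewalk

Hindered molecular diffusion in segmented cellular microstructures, from
image to transport coefficient.

Dense cellular aggregates — the motivating case is the platelet mass that
seals a vascular injury — hinder the diffusion of proteins and small
solutes through a tortuous network of narrow inter-cellular pores. High
resolution electron microscopy plus machine segmentation yields grayscale
maps of where the cells are; what a modeller needs is the *local effective
diffusivity* that such a microstructure imposes. `porewalk` closes that
gap for people who have segmentation output (or want to prototype against
synthetic microstructures) and need spatially resolved transport
coefficients:

1. **Binarization.** An 8-bit grayscale segmentation rendering (cell
   probability or gradient-flow map) is thresholded at a *brightness
   threshold value* (BTV): a pixel with brightness below the BTV becomes
   `cell`, otherwise `pore`.
2. **Lattice kinetic Monte Carlo (LKMC).** Non-interacting tracers hop
   between nearest-neighbour pore sites of the resulting lattice (spacing
   *h*, default 8 nm). The Next Reaction method drives the dynamics: every
   directional hop event of every particle carries a pre-drawn firing time

   *t*<sub>event</sub> = *t*<sub>sys</sub> − *h*² log(*r*) / *D*<sub>p</sub>,  *r* ~ U(0, 1],

   events execute in increasing time order, and hops into cell sites are
   inaccessible. Mirror boundary conditions reflect trajectories into
   tiled image copies so that no occupancy discontinuity is met at domain
   edges.
3. **Diffusivity estimation.** The mean squared displacement
   MSD(*t*) = (1/*n*) Σᵢ [**r**ᵢ(*t*) − **r**ᵢ(0)]² is sampled on unfolded
   coordinates and the 2D Einstein relation *D* = MSD/4*t* is applied as
   an ordinary least-squares slope over the late-time window (*t* ≥ 1 ms
   by default, excluding the early free-diffusion transient), averaged
   over 5 replicate runs of 1000 tracers.
4. **Analyses.** Functional calibration of the BTV against a
   manually-labelled ground truth (the threshold where *D*/*D*<sub>GT</sub>
   crosses 1), staggered-subdomain heatmaps of local *D*/*D*<sub>p</sub>
   and porosity (2 µm windows, 1 µm stagger: 81 subdomains and 100
   overlap-averaged values per 10 × 10 µm² field), pixelwise IoU scoring,
   and porosity–diffusivity pooling.

A seeded synthetic generator (`generate_packing()`) builds ellipse
packings with instance-labelled ground truth across the sparse (~0.33)
to dense (~0.11) porosity regimes, plus blurred/noisy pseudo-segmentation
maps, so every stage is testable without microscopy data.

## Worked example

```r
library(porewalk)

# a 2 x 2 um synthetic platelet packing at sparse porosity
pk <- generate_packing(extent_um = c(2, 2), target_porosity = 0.33,
                       mean_radius_um = 0.15, seed = 1)
porosity(pk$domain)
#> [1] 0.349792

# simulate tracer diffusion and estimate the hindered diffusivity
cfg <- sim_config(n_particles = 500, replicates = 3, seed = 1)
est <- run_replicates(pk$domain, cfg)
est
#> <diffusivity_estimate> D = 2.054e-07 cm2/s (D/D_p = 0.2054), sd = 2.39e-08 over 3 replicate(s)
#>   fit window [0.001, 0.003] s, n = 500 tracers
```

At porosity 0.35 the tracers retain ~21% of their free-water mobility
(*D*<sub>p</sub> = 1 × 10⁻⁶ cm²/s): the pore network is connected but
tortuous. `tidy(est)` gives the per-replicate values, `glance(est)` the
one-row summary, and `autoplot()` methods draw MSD curves, domains,
calibration sweeps and heatmaps.

Calibrating a threshold against ground truth:

```r
gray <- render_pseudo_map(pk$domain, blur_sigma_px = 2, noise_sd = 5, seed = 2)
sw <- btv_sweep(gray, pk$domain, btv_values = seq(20, 240, by = 20),
                config = sim_config(n_particles = 300, replicates = 3,
                                    t_end = 1e-3, t_fit_start = 3e-4))
glance(sw)
#> # A tibble: 1 × 4
#>   optimal_btv d_gt_cm2_s d_gt_relative n_btv
#>         <dbl>      <dbl>         <dbl> <int>
#> 1        94.1 0.000000255         0.255    12
```

The sweep finds the BTV (~94 here) at which the binarized map reproduces
the ground-truth diffusivity — the "functional accuracy" notion of
segmentation quality, which can disagree with pixel-overlap scores when
narrow pores are mis-resolved.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "porewalk.R", package = "porewalk"))') \
    synth --porosity 0.33 --extent-um 2 --seed 1 --out pack1
# then: binarize, simulate, sweep, heatmap, iou  (--help lists options)
```

Every subcommand writes a `<out>.config.yaml` with its fully resolved
parameters; `--config file.yaml` reads one back, and explicit flags
override it.

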