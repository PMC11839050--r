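---
title: "Methods: lattice kinetic Monte Carlo diffusion on binarized segmentation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice kinetic Monte Carlo diffusion on binarized segmentation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`porewalk` turns segmented images of densely packed cellular media into
quantitative transport predictions. This vignette explains the model, the
estimators, the parameter choices and their rationale, what the synthetic
generator does and does not emulate, and the numerical conventions a user
relying on the results should know.

## The physical model

The computational domain is a 2D square lattice whose sites are either
`pore` (accessible) or `cell` (excluded). Tracer molecules perform
nearest-neighbour hops with per-direction rate $D_p / h^2$, where $h$ is
the lattice spacing and $D_p$ the unhindered diffusivity. Tracers do not
interact with each other — each only sees the static cell boundaries — so
a run with $n$ particles is $n$ independent walks sharing one event
clock. The defaults are $h = 8$ nm (the pixel resolution of the
serial block-face SEM imagery this pipeline targets, which also sets an
effective tracer radius of one lattice site) and
$D_p = 1 \times 10^{-6}\ \mathrm{cm^2/s}$, a typical protein diffusivity
in water. $D_p$ only sets the clock: all reported *relative*
diffusivities $D/D_p$ depend purely on geometry.

### Event-driven dynamics

The engine implements the Next Reaction method. Each particle carries
four directional hop events with absolute firing times

$$t_{event} = t_{sys} - \frac{h^2 \log r}{D_p}, \qquad r \sim U(0,1],$$

i.e. exponential waits at rate $D_p/h^2$ per direction. The earliest
event in the system executes; the moved particle's four events are then
recalculated. Hops whose destination is a cell site are inaccessible
(sentinel-infinite firing time) and are re-examined after every move of
that particle, since its neighbourhood has changed. Two implementation
facts matter for correctness:

* Because *all four* events of the moved particle are redrawn and no
  other particle's events ever change (static obstacles, no
  interactions), only the per-particle minimum can ever fire. The
  compiled engine therefore keeps exactly one `(time, particle)` entry in
  the global priority queue — the law and the executed event sequence are
  identical to the literal four-events-per-particle queue, at a quarter
  of the queue traffic.
* Draws with $r = 0$ (which would give an infinite $-\log r$) are
  excluded by construction: the uniform generator is mapped onto $(0, 1]$.

A completely caged particle (all four neighbours are cell) is dropped
from the queue permanently; it can never move and obstacles never
disappear.

### Mirror boundary conditions

Finite images would otherwise truncate trajectories. The domain is
conceptually tiled with mirror images: an unfolded coordinate $x$ maps
onto the axis of length $W$ by triangle-wave reflection with period
$2W$ (`fold_index()`). Reflection — rather than periodic wrapping —
guarantees that the occupancy field is continuous across every boundary
for *any* irregular structure. Positions are tracked unfolded and the
fold is applied only to occupancy lookups, so displacements carry no wrap
artifacts. A useful consequence, exercised in the tests: an open (all
pore) domain of any size, however small, reproduces free diffusion on the
infinite lattice exactly.

### Diffusivity estimation

The mean squared displacement
$\mathrm{MSD}(t) = \frac{1}{n}\sum_i \lVert \mathbf r_i(t)-\mathbf r_i(0)\rVert^2$
is sampled on a fixed grid (`record_dt`, default $10^{-5}$ s, giving 300
samples over the default $t_{end} = 0.003$ s). In 2D,
$D = \mathrm{MSD}/4t$; the estimator is the ordinary least-squares slope
of MSD against time over $t \ge t_{fit\_start}$ (default 0.001 s),
divided by 4, with a free intercept. The window excludes the early
transient in which particles have not yet explored the hindered pore
space and so still diffuse at $\approx D_p$; the free intercept absorbs
whatever offset that transient leaves, which a forced-through-origin or
pointwise $\mathrm{MSD}/4t$ estimator would fold into the result.
Negative fitted slopes (possible in fully caged geometries with finite
sampling) are clamped to $D = 0$.

Each reported estimate averages `replicates` independent runs (default
5, seeded `seed`, `seed + 1`, …); the across-replicate standard deviation
is reported as `dispersion`. Everything is bit-reproducible for a fixed
seed within this implementation (the compiled engine uses its own
`mt19937_64` stream per replicate; R-level generators are isolated with
`withr::with_seed` and never touch the global RNG state).

### Validation against an independent walker

`reference_walk()` is a deliberately naive rejection-sampling walker,
written in plain vectorised R with no code shared with the engine: all
four directions are attempted at rate $D_p/h^2$ each, and attempts into
cell sites consume time without moving. For static obstacles this law is
identical to the Next-Reaction convention, so the two samplers must agree
in distribution. The acceptance suite compares final displacement
magnitudes with two-sample Kolmogorov–Smirnov tests on packings across
the dense-to-sparse regime.

Closed-form oracles complete the validation: an open lattice must give
$D = D_p$ ($\mathrm{MSD} = 4D_p t$); a width-1 pore channel is a 1D walk
and must report $D = D_p/2$ under the 2D estimator; a single pore site
gives $\mathrm{MSD} \equiv 0$.

## Binarization and its calibration

A grayscale map (RGB inputs are collapsed with the NTSC luma
$0.299R + 0.587G + 0.114B$, rounded half-up — half-up rather than
banker's rounding so the mapping is platform-stable and monotone) is
thresholded at an integer BTV in $[0, 256]$: brightness strictly below
the BTV becomes cell, everything else pore. The strict inequality
resolves equality at the threshold to pore; BTV = 0 therefore yields an
all-pore domain and BTV = 256 an all-cell one, and the cell-pixel count
is monotone in the BTV. A `cell_below_threshold = FALSE` polarity flag
inverts the rule for renderings in which cells are bright. The polarity
convention is exposed rather than hard-coded because rendered probability
and flow maps differ between tools in which extreme denotes "cell"; the
package default is the dark-cell convention.

Pixel-overlap accuracy is scored with pixelwise IoU (shared cell pixels
over the union; two masks with no cell pixels at all score 1, avoiding a
0/0). But overlap does not guarantee *functional* accuracy — resolving
the narrow pore necks that control transport. `btv_sweep()` therefore
calibrates the threshold functionally: it simulates the binarized domain
at each BTV and reports $D(\mathrm{BTV})/D_{GT}$ against the ground-truth
(manually labelled) domain, interpolating the first crossing of 1 in
increasing-BTV order as the optimal threshold. First-crossing with linear
interpolation is deterministic and matches the monotone-trend reading of
such sweeps; when replicate noise produces multiple crossings the first
is reported, and when no crossing exists the optimum is `NA` rather than
an extrapolation.

## Subdomain heatmaps

`diffusion_heatmap()` tiles the domain with square windows (default
2 µm) staggered by a stride (default 1 µm), runs a full
replicate-averaged simulation in each subdomain *as its own mirrored
lattice*, and overlap-averages onto stride-sized unit cells: a unit
cell's value is the mean over every window that *fully contains* it —
4 in the interior, 2 on edges, 1 at corners. On a 10 × 10 µm² field this
gives 81 subdomains and exactly 100 local values. Full containment (as
opposed to any-overlap) is what reproduces those counts. Porosity grids
are computed identically and exactly. Domains that are not a whole
number of windows are tiled with as many full windows as fit; trailing
remainder pixels are excluded and the resulting grid extent is recorded
in the object. Subdomain $k$ runs with seed offset $(k-1) \cdot
\texttt{replicates}$ so replicate streams never collide.

Treating each window as an isolated mirrored domain measures the *local*
hindrance of that neighbourhood; it deliberately ignores exchange with
surrounding regions, which is the standard trade-off of any windowed
transport estimate.

## The synthetic generator

`generate_packing()` emulates the two packing regimes reported for
platelet masses — sparse (porosity ≈ 0.33) and dense (≈ 0.11) — by
sequential random insertion of non-overlapping ellipses (the idealised
platelet shape in cross-section): candidate centres are drawn uniformly
over still-free pixels, sizes from a lognormal (mean radius 0.5 µm,
CV 0.35), aspect ratios uniform in [1.2, 3], orientation uniform.
A candidate whose footprint, dilated by `min_gap_px`, touches an
existing particle is rejected; repeated rejection anneals the proposal
radius downwards (×0.92 per 15 consecutive failures, floored at ~1.3 px
with near-round shapes below 4 px, since elongated slivers do not
rasterise), so progressively smaller particles — platelet fragments, in
effect — fill the gaps until the target porosity (+0.02 stopping margin)
is reached. The default `min_gap_px = 0` lets particles touch but never
overlap, matching contact-dominated dense packings; a positive gap
instead guarantees a connected inter-particle pore network. Generation
is deterministic per seed, and the achieved porosity lands within ±0.05
of targets throughout the 0.1–0.6 range.

What the generator does *not* emulate: real platelet deformation and
concavity, fibrin fibres, red-cell inclusions, anisotropic packing, and
3D structure. Tests passing on these packings therefore demonstrate the
*pipeline's* correctness (binarization, simulation, estimation,
averaging), not that any particular biological image will calibrate at a
particular threshold.

`render_pseudo_map()` paints a domain cell = 0 / pore = 255, applies a
Gaussian blur (edge mode: replicate) to soften boundaries as rendered
probability/flow maps do, and adds clipped Gaussian noise. With zero
blur and zero noise the rendering binarizes back to the exact domain at
any interior threshold — the identity that anchors the calibration
tests.

## Numerical conventions and problem sizes

* Internal units are nm and s; $D_p$ converts at
  $1\ \mathrm{cm^2} = 10^{14}\ \mathrm{nm^2}$. Reported diffusivities are
  cm²/s or dimensionless $D/D_p$.
* MSD is accumulated in integer lattice units inside the compiled loop
  (exact; no floating-point drift) and scaled by $h^2$ on output.
* Grid-resolution resampling (`resample_domain()`) is conservative: a
  coarse site is pore only if every constituent fine site is pore, so
  porosity never increases and effective tracer size grows with the
  factor.
* The acceptance suite runs the full published protocol where it is
  cheap enough to be routine — open-lattice and channel oracles at
  1250 × 1250 with $n = 1000$ and 5 replicates — and scaled-down problem
  sizes elsewhere (subdomain collapse at 2 × 2 µm with $n = 200$, KS
  comparisons at $n = 500$ on 1.6 µm packings, reduced tracer counts for
  the pure counting checks). The scaled-down sizes were chosen once as
  the smallest at which the targeted effect is comfortably above Monte
  Carlo noise.
* Unit tests use shorter horizons still (`t_end` 0.2–1 ms) with
  proportionally earlier fit windows; the estimator is
  horizon-independent for the geometries tested.

## Known limitations

* 2D only: diffusivities are in-plane values for a section, not 3D
  transport coefficients; vertical escape paths are absent, so hindrance
  is systematically overestimated relative to a 3D structure.
* Non-interacting tracers: no crowding, binding, advection or reaction.
* The BTV calibration is as good as the ground truth it is matched
  against, and the optimum is image-class dependent for cell-probability
  style maps; it should be recalibrated per rendering convention.
* Windowed local diffusivities are not wired into a whole-domain
  effective-medium estimate; pooling across windows
  (`porosity_diffusivity_table()`) is provided for the porosity collapse
  instead.
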