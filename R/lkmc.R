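# User-facing surface of the lattice kinetic Monte Carlo engine:
# configuration, simulation, MSD-slope diffusivity estimation, replicates.

CM2_PER_NM2 <- 1e-14  # 1 cm^2 = 1e14 nm^2

#' Simulation configuration
#'
#' Collects every parameter of a tracer-diffusion run. Defaults follow the
#' standard protocol for intrathrombus diffusion on 8 nm segmentation
#' lattices: unhindered diffusivity \eqn{D_p = 1 \times 10^{-6}} cm²/s
#' (typical for a protein in water), 1000 tracers, evolution to
#' \eqn{t = 0.003} s, diffusivity fitted on the MSD at \eqn{t \ge 0.001} s
#' only (the early transient reflects free diffusion before tracers have
#' explored the hindered pore space), and 5 duplicate runs.
#'
#' @param D_p Unhindered tracer diffusivity in cm²/s.
#' @param n_particles Number of non-interacting tracers per run.
#' @param t_end Simulated duration in seconds.
#' @param t_fit_start Start of the MSD fit window in seconds.
#' @param record_dt MSD sampling interval in seconds.
#' @param replicates Number of duplicate runs averaged per estimate.
#' @param seed Base RNG seed; replicate k uses `seed + k - 1`.
#' @return A `sim_config` list.
#' @examples
#' sim_config(n_particles = 100, replicates = 2)
#' @export
sim_config <- function(D_p = 1e-6, n_particles = 1000, t_end = 0.003,
                       t_fit_start = 0.001, record_dt = 1e-5,
                       replicates = 5, seed = 1) {
  if (D_p <= 0) rlang::abort("D_p must be positive")
  if (n_particles < 1) rlang::abort("n_particles must be >= 1")
  if (t_end <= 0) rlang::abort("t_end must be positive")
  if (t_fit_start <= 0 || t_fit_start >= t_end) {
    rlang::abort("t_fit_start must lie in (0, t_end)")
  }
  if (record_dt <= 0) rlang::abort("record_dt must be positive")
  if (replicates < 1) rlang::abort("replicates must be >= 1")
  structure(
    list(D_p = D_p, n_particles = as.integer(n_particles), t_end = t_end,
         t_fit_start = t_fit_start, record_dt = record_dt,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> D_p = %g cm2/s, n = %d, t_end = %g s (fit from %g s, dt %g s), %d replicate(s), seed %d\n",
    x$D_p, x$n_particles, x$t_end, x$t_fit_start, x$record_dt, x$replicates,
    x$seed))
  invisible(x)
}

#' Mirror-boundary index folding
#'
#' Maps an unfolded integer coordinate onto a finite axis of length `W` by
#' triangle-wave reflection with period `2W`: the infinite plane is tiled
#' with mirror images of the domain, so trajectories cross boundaries
#' without encountering any occupancy discontinuity. 0-based on both sides.
#'
#' @param x Integer vector of unfolded coordinates.
#' @param W Axis length (>= 1).
#' @return Integer vector of folded indices in `[0, W)`.
#' @examples
#' fold_index(c(-1, 0, 3, 4, 7, 8), 4)
#' @export
fold_index <- function(x, W) {
  if (!is.numeric(W) || length(W) != 1 || W < 1) rlang::abort("W must be >= 1")
  .lkmc_fold_index(as.integer(x), as.integer(W))
}

#' Next-reaction event time
#'
#' The firing time of one directional hop event:
#' \eqn{t_{event} = t_{sys} - h^2 \log(r) / D}, with `r` uniform on
#' `(0, 1]`, i.e. an exponential waiting time with per-direction rate
#' \eqn{D / h^2}.
#'
#' @param t_sys Current system time (s).
#' @param h_nm Lattice spacing in nm.
#' @param D_nm2_s Diffusivity in nm²/s (note the lattice-level units;
#'   `1e-6` cm²/s is `1e8` nm²/s).
#' @param r Uniform draw in `(0, 1]` (vectorised).
#' @return Event time(s), always `>= t_sys`.
#' @examples
#' schedule_event(0, h_nm = 8, D_nm2_s = 1e8, r = exp(-1))  # 6.4e-7 s
#' @export
schedule_event <- function(t_sys, h_nm, D_nm2_s, r) {
  if (any(r <= 0) || any(r > 1)) {
    rlang::abort("r must lie in (0, 1]; a zero draw must be redrawn")
  }
  if (h_nm <= 0 || D_nm2_s <= 0) rlang::abort("h and D must be positive")
  t_sys + h_nm^2 * (-log(r)) / D_nm2_s
}

#' Simulate tracer diffusion on a binary domain
#'
#' Runs the event-driven Next Reaction engine: `n_particles` tracers are
#' placed i.i.d. uniformly over pore sites, each carries four directional
#' hop events with exponentially distributed firing times at per-direction
#' rate \eqn{D_p/h^2}, events execute in increasing time order, and a moved
#' particle's events are recalculated. Hops into cell sites are
#' inaccessible. Mirror boundary conditions let trajectories continue into
#' reflected copies of the domain; displacement is tracked unfolded, so the
#' mean squared displacement (MSD) is free of wrap artifacts.
#'
#' @param domain A [binary_domain()] with at least one pore site.
#' @param config A [sim_config()]; its `seed` (or the `seed` argument) fixes
#'   the run exactly.
#' @param seed Optional override of `config$seed`.
#' @param keep_displacements If `TRUE`, attach per-particle positions as
#'   attribute `"displacements"`: a tibble with unfolded 0-based origin
#'   (`x0`, `y0`) and final (`x`, `y`) lattice coordinates plus
#'   displacements in nm (`dx_nm`, `dy_nm`) — used for distributional
#'   validation.
#' @return An `msd_series` tibble with columns `time_s`, `msd_nm2`
#'   (starting at the origin `(0, 0)`), carrying attributes `spacing_nm`,
#'   `n_particles`, `n_events` and `seed`.
#' @examples
#' dom <- generate_canonical("empty", dim = c(32, 32))
#' cfg <- sim_config(n_particles = 50, t_end = 5e-4, t_fit_start = 1e-4)
#' simulate_tracers(dom, cfg)
#' @export
simulate_tracers <- function(domain, config = sim_config(), seed = NULL,
                             keep_displacements = FALSE) {
  stopifnot(inherits(domain, "binary_domain"), inherits(config, "sim_config"))
  if (!any(domain$pore)) rlang::abort("domain has no pore sites")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  h <- domain$spacing_nm
  res <- .lkmc_simulate(domain$pore, h, config$D_p / CM2_PER_NM2,
                        config$n_particles, config$t_end, config$record_dt,
                        as.double(seed))
  out <- tibble::tibble(time_s = c(0, res$times), msd_nm2 = c(0, res$msd_nm2))
  attr(out, "spacing_nm") <- h
  attr(out, "n_particles") <- config$n_particles
  attr(out, "n_events") <- res$n_events
  attr(out, "seed") <- seed
  if (keep_displacements) {
    attr(out, "displacements") <- tibble::tibble(
      x0 = res$x0, y0 = res$y0, x = res$x, y = res$y,
      dx_nm = (res$x - res$x0) * h, dy_nm = (res$y - res$y0) * h)
  }
  class(out) <- c("msd_series", class(out))
  out
}

#' Estimate diffusivity from an MSD series
#'
#' In two dimensions \eqn{D = MSD(t) / 4t}; the estimator used here is the
#' ordinary least-squares slope of MSD against time, restricted to times at
#' or beyond the fit-window start, divided by 4. The intercept is left
#' free so that the short-time free-diffusion offset excluded from the
#' window does not bias the slope.
#'
#' @param msd An `msd_series` from [simulate_tracers()], or any data frame
#'   with columns `time_s` and `msd_nm2`.
#' @param config A [sim_config()] supplying `t_fit_start` and `D_p`.
#' @return A one-replicate `diffusivity_estimate` (see [run_replicates()]).
#' @export
estimate_diffusivity <- function(msd, config = sim_config()) {
  stopifnot(is.data.frame(msd), inherits(config, "sim_config"))
  win <- msd[msd$time_s >= config$t_fit_start, , drop = FALSE]
  if (nrow(win) < 2) {
    rlang::abort("fewer than 2 MSD samples at or beyond t_fit_start")
  }
  slope_nm2_s <- stats::cov(win$time_s, win$msd_nm2) / stats::var(win$time_s)
  D <- max(slope_nm2_s / 4, 0) * CM2_PER_NM2
  new_diffusivity_estimate(
    D = D, config = config,
    replicate_values = tibble::tibble(
      replicate = 1L,
      seed = attr(msd, "seed") %||% NA_integer_,
      D_cm2_s = D, D_relative = D / config$D_p),
    msd = msd)
}

new_diffusivity_estimate <- function(D, config, replicate_values, msd = NULL) {
  structure(
    list(D = D,
         D_relative = D / config$D_p,
         dispersion = if (nrow(replicate_values) > 1) {
           stats::sd(replicate_values$D_cm2_s)
         } else {
           0
         },
         replicate_values = replicate_values,
         fit_window = c(config$t_fit_start, config$t_end),
         config = config,
         msd = msd),
    class = "diffusivity_estimate")
}

#' Replicate-averaged diffusivity of a domain
#'
#' Runs [simulate_tracers()] + [estimate_diffusivity()] `config$replicates`
#' times with seeds `seed, seed + 1, ...`, and reports the mean diffusivity
#' with the across-replicate standard deviation as dispersion. Fully
#' reproducible for a fixed seed.
#'
#' @param domain A [binary_domain()].
#' @param config A [sim_config()].
#' @param keep_msd If `TRUE`, keep the concatenated per-replicate MSD series
#'   (tibble with a `replicate` column) in the result.
#' @return A `diffusivity_estimate` with fields `D` (cm²/s), `D_relative`
#'   (`D / D_p`), `dispersion`, `replicate_values` (tibble), `fit_window`
#'   and `config`. Use [tidy()][generics::tidy] / [glance()][generics::glance]
#'   for tabular views.
#' @examples
#' dom <- generate_canonical("empty", dim = c(32, 32))
#' cfg <- sim_config(n_particles = 50, t_end = 5e-4, t_fit_start = 1e-4,
#'                   replicates = 2)
#' run_replicates(dom, cfg)
#' @export
run_replicates <- function(domain, config = sim_config(), keep_msd = FALSE) {
  stopifnot(inherits(domain, "binary_domain"), inherits(config, "sim_config"))
  reps <- purrr::map(seq_len(config$replicates), function(k) {
    s <- config$seed + k - 1L
    msd <- simulate_tracers(domain, config, seed = s)
    est <- estimate_diffusivity(msd, config)
    list(D = est$D, seed = s, msd = if (keep_msd) msd else NULL)
  })
  replicate_values <- tibble::tibble(
    replicate = seq_len(config$replicates),
    seed = purrr::map_int(reps, "seed"),
    D_cm2_s = purrr::map_dbl(reps, "D"),
    D_relative = purrr::map_dbl(reps, "D") / config$D_p)
  msd <- if (keep_msd) {
    dplyr::bind_rows(purrr::imap(reps, function(r, k) {
      dplyr::mutate(tibble::as_tibble(r$msd), replicate = k, .before = 1)
    }))
  }
  new_diffusivity_estimate(D = mean(replicate_values$D_cm2_s), config = config,
                           replicate_values = replicate_values, msd = msd)
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf(
    "<diffusivity_estimate> D = %.4g cm2/s (D/D_p = %.4f), sd = %.3g over %d replicate(s)\n",
    x$D, x$D_relative, x$dispersion, nrow(x$replicate_values)))
  cat(sprintf("  fit window [%g, %g] s, n = %d tracers\n",
              x$fit_window[1], x$fit_window[2], x$config$n_particles))
  invisible(x)
}

#' Rejection-sampling reference walker
#'
#' An intentionally simple, fully independent random-walk implementation
#' used to validate the event-driven engine: every tracer attempts hops in
#' all four directions at rate \eqn{D_p/h^2} each (waiting times drawn per
#' attempt), and attempts whose mirror-folded destination is a cell site
#' consume time without moving. For static obstacles this law coincides
#' with the Next Reaction convention, so final-displacement distributions
#' from the two walkers must agree. Written in plain vectorised R with no
#' shared code path with the compiled engine.
#'
#' @param domain A [binary_domain()].
#' @param config A [sim_config()] (only `D_p`, `n_particles`, `t_end` used).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A tibble with per-particle final displacements `dx_nm`, `dy_nm`.
#' @export
reference_walk <- function(domain, config = sim_config(), seed = NULL) {
  stopifnot(inherits(domain, "binary_domain"), inherits(config, "sim_config"))
  if (!any(domain$pore)) rlang::abort("domain has no pore sites")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  pore <- domain$pore
  H <- nrow(pore); W <- ncol(pore)
  h <- domain$spacing_nm
  rate_total <- 4 * (config$D_p / CM2_PER_NM2) / h^2
  n <- config$n_particles
  withr::with_seed(seed, {
    sites <- which(pore)
    start <- sites[sample.int(length(sites), n, replace = TRUE)]
    x0 <- (start - 1L) %/% H   # 0-based column
    y0 <- (start - 1L) %% H    # 0-based row
    x <- x0; y <- y0
    t <- numeric(n)
    active <- rep(TRUE, n)
    dx4 <- c(1L, -1L, 0L, 0L); dy4 <- c(0L, 0L, 1L, -1L)
    while (any(active)) {
      idx <- which(active)
      t[idx] <- t[idx] + stats::rexp(length(idx), rate = rate_total)
      active[idx] <- t[idx] <= config$t_end
      mov <- idx[active[idx]]
      if (length(mov) == 0) next
      d <- sample.int(4L, length(mov), replace = TRUE)
      nx <- x[mov] + dx4[d]
      ny <- y[mov] + dy4[d]
      ok <- pore[cbind(fold_index(ny, H) + 1L, fold_index(nx, W) + 1L)]
      x[mov[ok]] <- nx[ok]
      y[mov[ok]] <- ny[ok]
    }
    tibble::tibble(dx_nm = (x - x0) * h, dy_nm = (y - y0) * h)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
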