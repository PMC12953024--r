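#' Build a regular 2-D tissue grid (or 1-D cable)
#'
#' Regular quadrilateral mesh with fibres along +x. The printed
#' conductivities are treated as the effective monodomain tensor (the
#' lambda/(1+lambda) factor already folded in); the diffusivity used by the
#' solver is sigma / (Am Cm).
#'
#' @param nx,ny Element counts along x and y (ny = 1 gives a cable).
#' @param dx Element edge length (um, default 400).
#' @param sigma_l,sigma_t Longitudinal / transverse effective monodomain
#'   conductivities (S/m).
#' @param Am Surface-to-volume ratio (1/cm).
#' @param Cm Membrane capacitance (uF/cm^2).
#' @return A `tissue_grid` object.
#' @examples
#' g <- build_sheet(150, 150)           # 6 x 6 cm at 400 um
#' g$nx * g$dx_cm                       # 6 cm
#' @export
build_sheet <- function(nx, ny = 1, dx = 400, sigma_l = 0.1608,
                        sigma_t = 0.0448, Am = 1400, Cm = 1) {
  stopifnot(nx >= 1, ny >= 1, dx > 0, sigma_l >= sigma_t, sigma_t > 0)
  g <- list(nx = as.integer(nx), ny = as.integer(ny), dx_cm = dx * 1e-4,
            sigma_l = sigma_l, sigma_t = sigma_t, Am = Am, Cm = Cm)
  class(g) <- "tissue_grid"
  g
}

#' Grid from physical sheet dimensions
#'
#' @param lx_cm,ly_cm Sheet dimensions (cm).
#' @param dx Element edge (um).
#' @param ... Passed to [build_sheet()].
#' @return A `tissue_grid`; 6 x 6 cm at 400 um gives 150 x 150 elements.
#' @export
sheet_from_cm <- function(lx_cm, ly_cm = 0, dx = 400, ...) {
  nx <- round(lx_cm / (dx * 1e-4))
  ny <- max(1L, round(ly_cm / (dx * 1e-4)))
  build_sheet(nx, ny, dx = dx, ...)
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %d x %d elements, dx = %g um (%.2f x %.2f cm)\n",
              x$nx, x$ny, x$dx_cm * 1e4, x$nx * x$dx_cm, x$ny * x$dx_cm))
  cat(sprintf("  sigma_l = %g, sigma_t = %g S/m (anisotropy %.2f)\n",
              x$sigma_l, x$sigma_t, x$sigma_l / x$sigma_t))
  invisible(x)
}

n_elements <- function(grid) grid$nx * grid$ny

# diffusivity in cm^2/ms: sigma [S/m] * 0.01 -> S/cm; / (Am Cm [uF/cm^3])
# gives S cm^2/uF = 1e3 cm^2/ms
diffusivity <- function(grid) {
  c(Dl = grid$sigma_l * 10 / (grid$Am * grid$Cm),
    Dt = grid$sigma_t * 10 / (grid$Am * grid$Cm))
}

node_index <- function(grid, ix, iy = 1) (iy - 1) * grid$nx + ix

node_x_cm <- function(grid, ix) (ix - 0.5) * grid$dx_cm

#' Random uniform adrenergic-stimulation map
#'
#' Flags `round(density * n_elements)` elements, sampled uniformly without
#' replacement with the given seed; all flagged elements share one ISO
#' concentration.
#'
#' @param grid A [build_sheet()] grid.
#' @param density Fraction of elements stimulated, in \[0, 1\].
#' @param seed Integer seed (reproducible maps).
#' @param iso ISO concentration (uM) on flagged elements.
#' @return A `bars_map`: logical flag vector plus metadata.
#' @examples
#' m <- assign_bars_density(build_sheet(150, 150), 0.05, seed = 1, iso = 0.1)
#' sum(m$flag)   # 1125
#' @export
assign_bars_density <- function(grid, density, seed = 1, iso = 0.1) {
  stopifnot(density >= 0, density <= 1)
  nn <- n_elements(grid)
  k <- round(density * nn)
  flag <- rep(FALSE, nn)
  if (k > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    flag[sample.int(nn, k)] <- TRUE
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(list(flag = flag, iso = iso, density = density, seed = seed,
                 delta = NULL, nx = grid$nx, ny = grid$ny),
            class = "bars_map")
}

#' Three-region adrenergic-stimulation gradient map
#'
#' Splits the sheet into three equal vertical regions along x. The centre
#' region has the base density (20 percent); the left region has
#' `base - delta` (floored at 0, with a warning when clamped) and the right
#' region `base + delta`. Elements are sampled independently per region
#' under one seed.
#'
#' @param grid Grid whose nx is divisible by 3 (e.g. the 9 x 6 cm sheet,
#'   225 x 150 elements).
#' @param delta Density gradient step (fraction, e.g. 0.05 to 0.20).
#' @param seed Integer seed.
#' @param iso ISO concentration (uM) on flagged elements.
#' @param base Centre-region density (default 0.20).
#' @return A `bars_map`.
#' @export
assign_bars_gradient <- function(grid, delta, seed = 1, iso = 0.1,
                                 base = 0.20) {
  stopifnot(delta >= 0)
  if (grid$nx %% 3 != 0) stop("nx must be divisible by 3 for three regions")
  lo <- base - delta
  if (lo < 0) {
    warning("left-region density clamped at 0")
    lo <- 0
  }
  dens <- c(lo, base, base + delta)
  nn <- n_elements(grid)
  flag <- rep(FALSE, nn)
  w <- grid$nx / 3
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (r in 1:3) {
    cols <- ((r - 1) * w + 1):(r * w)
    idx <- as.vector(outer(cols, (0:(grid$ny - 1)) * grid$nx, `+`))
    k <- round(dens[r] * length(idx))
    if (k > 0) flag[sample(idx, k)] <- TRUE
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(flag = flag, iso = iso, density = NULL, seed = seed,
                 delta = delta, base = base, region_density = dens,
                 nx = grid$nx, ny = grid$ny),
            class = "bars_map")
}

#' @export
print.bars_map <- function(x, ...) {
  cat(sprintf("<bars_map> %d x %d, %d flagged (%.1f%%), ISO = %g uM, seed %d\n",
              x$nx, x$ny, sum(x$flag), 100 * mean(x$flag), x$iso, x$seed))
  invisible(x)
}

#' Transmembrane stimulus specification for tissue runs
#'
#' @param region Element indices (1-based, x fastest) receiving the pulse.
#' @param amplitude Amplitude in pA/pF (cell-equivalent). Use
#'   [stim_amp_from_uAcm3()] to convert a volumetric density.
#' @param onset First pulse onset (ms).
#' @param dur Pulse width (ms).
#' @param cycle_length Period for repeated pulses (ms, 0 = single pulse).
#' @param npulses Number of pulses.
#' @return A `stimulus_spec` list.
#' @export
tissue_stimulus <- function(region, amplitude, onset = 0, dur = 2,
                            cycle_length = 0, npulses = 1) {
  stopifnot(length(region) > 0, dur > 0)
  structure(list(region = as.integer(region), amplitude = amplitude,
                 onset = onset, dur = dur, cycle_length = cycle_length,
                 npulses = as.integer(npulses)), class = "stimulus_spec")
}

#' Convert a volumetric stimulus density to a cell-equivalent density
#'
#' I (uA/cm^3) / (Am Cm) gives pA/pF.
#' @param amp_uAcm3 Stimulus density (uA/cm^3 tissue).
#' @param grid Grid providing Am (1/cm) and Cm (uF/cm^2).
#' @return Amplitude in pA/pF.
#' @export
stim_amp_from_uAcm3 <- function(amp_uAcm3, grid) {
  amp_uAcm3 / (grid$Am * grid$Cm)
}

#' Per-node initial states from the single-cell limit cycle
#'
#' Paces a single cell at the given basic cycle length (600 ms reference)
#' separately for ISO = 0 and for the map's ISO, then assigns each node the
#' end-diastolic state matching its adrenergic-stimulation flag.
#'
#' @param grid Tissue grid.
#' @param barsmap A `bars_map`, or `NULL` for a uniform sheet at `iso`.
#' @param iso Uniform ISO (uM) when `barsmap` is `NULL`.
#' @param pcl Pre-pacing cycle length (ms).
#' @param pre_beats Pre-pacing beats (100 beats at 600 ms is 60 s).
#' @param amplitude,pulse_ms,dt,curves,mods See [pace_to_steady_state()].
#' @return Matrix n_elements x 26 of initial states.
#' @export
tissue_init_states <- function(grid, barsmap = NULL, iso = 0, pcl = 600,
                               pre_beats = 100, amplitude = 60,
                               pulse_ms = 0.5, dt = 0.02,
                               curves = dose_response_curves(),
                               mods = bars_modifiers()) {
  nn <- n_elements(grid)
  iso_on <- if (is.null(barsmap)) iso else barsmap$iso
  p0 <- pace_to_steady_state(0, pcl = pcl, n_beats = pre_beats,
                             amplitude = amplitude, pulse_ms = pulse_ms,
                             dt = dt, curves = curves, mods = mods)
  s0 <- p0$final_state
  if (iso_on > 0) {
    p1 <- pace_to_steady_state(iso_on, pcl = pcl, n_beats = pre_beats,
                               amplitude = amplitude, pulse_ms = pulse_ms,
                               dt = dt, curves = curves, mods = mods)
    s1 <- p1$final_state
  } else s1 <- s0
  flags <- if (is.null(barsmap)) rep(iso > 0, nn) else barsmap$flag
  states <- matrix(rep(s0, each = nn), nrow = nn)
  if (any(flags)) states[flags, ] <- matrix(rep(s1, each = sum(flags)),
                                            nrow = sum(flags))
  states
}

#' Monodomain reaction-diffusion simulation
#'
#' Operator-split explicit integration: each node advances by the ionic
#' model (with that node's ISO: flagged elements get the map's ISO,
#' unflagged get 0) and the transmembrane potential diffuses with the
#' anisotropic 5-point Laplacian (fibres along x) under zero-flux
#' boundaries. Stimulus currents are cell-equivalent densities (pA/pF).
#'
#' @param grid Tissue grid.
#' @param stimuli A `stimulus_spec` or list of them.
#' @param duration Simulated time (ms).
#' @param barsmap `bars_map` or `NULL` (uniform at `iso`).
#' @param iso Uniform ISO when `barsmap` is `NULL` (uM).
#' @param init Initial states: matrix from [tissue_init_states()], a single
#'   26-vector recycled to all nodes, or `NULL` for the resting state.
#' @param dt Time step for both reaction and diffusion (ms).
#' @param frame_dt Vm frame sampling interval (ms).
#' @param probes Node indices recorded at fine resolution (1-based).
#' @param trace_dt Probe sampling interval (ms).
#' @param scale_map Optional list with per-element `gks` / `gkr` conductance
#'   multipliers (APD-modifier comparator substrates).
#' @param curves,mods,bars See [integrate_cell()].
#' @return A `tissue_recording`: frames (time x node Vm matrix), frame
#'   times, fine probe traces, per-node activation times (upstroke
#'   crossings of -20 mV), final states and grid metadata.
#' @export
monodomain_simulate <- function(grid, stimuli, duration, barsmap = NULL,
                                iso = 0, init = NULL, dt = 0.02,
                                frame_dt = 2, probes = integer(0),
                                trace_dt = dt, scale_map = NULL,
                                curves = dose_response_curves(),
                                mods = bars_modifiers(), bars = TRUE) {
  nn <- n_elements(grid)
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (is.null(init)) init <- cell_state()
  if (is.null(dim(init))) init <- matrix(rep(as.numeric(init), each = nn),
                                         nrow = nn)
  if (!is.null(barsmap) &&
      (barsmap$nx != grid$nx || barsmap$ny != grid$ny))
    stop("bars_map dimensions do not match the grid")
  iso_on <- if (is.null(barsmap)) iso else barsmap$iso
  flags <- if (is.null(barsmap)) rep(iso > 0, nn) else barsmap$flag
  alpha_tab <- rbind(as_alpha(phosphorylation_profile(0, curves)),
                     as_alpha(phosphorylation_profile(iso_on, curves)))
  alpha_idx <- as.integer(flags)            # 0-based row index for C++
  D <- diffusivity(grid)
  # explicit-diffusion stability bound
  cfl <- dt * (D["Dl"] + D["Dt"]) / grid$dx_cm^2
  if (cfl > 0.5) stop(sprintf("diffusion CFL number %.2f too large", cfl))
  ss <- lapply(stimuli, function(s) list(
    nodes = s$region - 1L, onset = s$onset, period = s$cycle_length,
    npulses = s$npulses, dur = s$dur, amp = s$amplitude))
  gks <- if (!is.null(scale_map$gks)) rep_len(scale_map$gks, nn) else rep(1, nn)
  gkr <- if (!is.null(scale_map$gkr)) rep_len(scale_map$gkr, nn) else rep(1, nn)
  raw <- cpp_tissue(init, alpha_idx, alpha_tab, mods, bars,
                    grid$nx, grid$ny, grid$dx_cm, D[["Dl"]], D[["Dt"]],
                    ss, dt, duration, frame_dt, as.integer(probes - 1L),
                    trace_dt, gks, gkr)
  rec <- list(frames = raw$frames, frame_time = raw$frame_time,
              probe_vm = raw$probe_vm, probe_time = raw$probe_time,
              probes = probes, final_states = raw$final_states,
              activations = raw$activations,
              n_activations = raw$n_activations,
              grid = grid, iso = iso_on, barsmap = barsmap, dt = dt,
              frame_dt = frame_dt)
  class(rec) <- "tissue_recording"
  rec
}

#' @export
print.tissue_recording <- function(x, ...) {
  cat(sprintf("<tissue_recording> %d x %d grid, %d frames (%.0f ms, every %g ms)\n",
              x$grid$nx, x$grid$ny, nrow(x$frames),
              max(x$frame_time), x$frame_dt))
  invisible(x)
}

probe_column <- function(rec, node) {
  i <- match(node, rec$probes)
  if (is.na(i)) stop("node ", node, " was not recorded as a probe")
  i
}

activation_time_probe <- function(rec, node, window = c(-Inf, Inf),
                                  min_upstroke = 5) {
  i <- probe_column(rec, node)
  tm <- rec$probe_time; vm <- rec$probe_vm[, i]
  sel <- tm >= window[1] & tm <= window[2]
  tm <- tm[sel]; vm <- vm[sel]
  if (length(tm) < 3) return(NA_real_)
  dv <- diff(vm) / diff(tm)
  k <- which.max(dv)
  if (dv[k] < min_upstroke) return(NA_real_)
  tm[k + 1]
}

repol_time_probe <- function(rec, node, window = c(-Inf, Inf), level = 0.9) {
  i <- probe_column(rec, node)
  tm <- rec$probe_time; vm <- rec$probe_vm[, i]
  sel <- tm >= window[1] & tm <= window[2]
  tm <- tm[sel]; vm <- vm[sel]
  vd <- vm[1]; ipk <- which.max(vm); vpk <- vm[ipk]
  if (vpk < 0) return(NA_real_)
  v90 <- vpk - level * (vpk - vd)
  idx <- which(vm[-seq_len(ipk)] <= v90)
  if (!length(idx)) return(NA_real_)
  i1 <- ipk + idx[1]; i0 <- i1 - 1
  frac <- (vm[i0] - v90) / (vm[i0] - vm[i1])
  tm[i0] + frac * (tm[i1] - tm[i0])
}

#' Conduction velocity on a cable from two probe activation times
#'
#' Activation time at each probe is the time of maximum dVm/dt within the
#' measurement window; CV is the probe separation over the activation-time
#' difference.
#'
#' @param recording A cable `tissue_recording` whose probes include the two
#'   measurement positions.
#' @param x1,x2 Probe positions (cm along the cable).
#' @param window Time window (ms) containing exactly one propagating beat.
#' @return CV in cm/s, or `NA` (with a warning) on conduction block.
#' @export
measure_cable_cv <- function(recording, x1 = 0.25, x2 = 0.75,
                             window = c(-Inf, Inf)) {
  g <- recording$grid
  n1 <- node_index(g, round(x1 / g$dx_cm + 0.5))
  n2 <- node_index(g, round(x2 / g$dx_cm + 0.5))
  t1 <- activation_time_probe(recording, n1, window)
  t2 <- activation_time_probe(recording, n2, window)
  if (is.na(t1) || is.na(t2) || t2 <= t1) {
    warning("conduction block between probes; CV undefined")
    return(NA_real_)
  }
  dx <- node_x_cm(g, round(x2 / g$dx_cm + 0.5)) -
        node_x_cm(g, round(x1 / g$dx_cm + 0.5))
  1000 * dx / (t2 - t1)
}

cable_probe_nodes <- function(grid, x = c(0.25, 0.75)) {
  vapply(x, function(xx)
    as.integer(node_index(grid, round(xx / grid$dx_cm + 0.5))), integer(1))
}

#' Minimal capturing stimulus amplitude on a cable
#'
#' Bisects the amplitude of a single 5 ms edge pulse until the wave just
#' propagates to the distal probe.
#'
#' @param grid Cable grid.
#' @param state0 Per-node initial states (or single state vector).
#' @param iso Uniform ISO (uM).
#' @param dur Pulse width (ms).
#' @param lo,hi Bracketing amplitudes (pA/pF).
#' @param iters Bisection iterations.
#' @param ... Passed to [monodomain_simulate()].
#' @return Threshold amplitude (pA/pF).
#' @export
capture_threshold <- function(grid, state0, iso = 0, dur = 5, lo = 1,
                              hi = 60, iters = 7, ...) {
  probes <- cable_probe_nodes(grid)
  captures <- function(amp) {
    s <- tissue_stimulus(region = 1:2, amplitude = amp, onset = 0, dur = dur)
    r <- monodomain_simulate(grid, s, duration = 150, iso = iso,
                             init = state0, probes = probes,
                             frame_dt = 50, ...)
    !is.na(activation_time_probe(r, probes[2]))
  }
  if (!captures(hi)) stop("upper bracket does not capture")
  if (captures(lo)) return(lo)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Calibrate cable conductivities to a target conduction velocity
#'
#' Bisection on a common multiplier of the (sigma_l, sigma_t) pair until the
#' measured longitudinal CV on the 1 cm cable is within `tol` of the
#' target. The multiplier absorbs discretization-induced deviation from the
#' continuous-cable values.
#'
#' @param grid Cable grid holding the starting conductivity pair.
#' @param target_cv Target CV (cm/s).
#' @param cell_state0 Pre-paced single-cell state used to initialise the
#'   cable (computed at 1 Hz, ISO = 0 when `NULL`).
#' @param iso Uniform ISO during calibration (uM).
#' @param s1_amp Stimulus amplitude (pA/pF); `NULL` uses twice the capture
#'   threshold.
#' @param n_s1 Conditioning beats before the measured beat.
#' @param tol Relative CV tolerance.
#' @param mult_range Bracketing interval for the multiplier.
#' @param verbose Print the multiplier found.
#' @param ... Passed to [monodomain_simulate()].
#' @return The grid with calibrated `sigma_l`, `sigma_t`, plus attributes
#'   `multiplier`, `cv` and `s1_amp`.
#' @export
calibrate_conductivities <- function(grid, target_cv = 60,
                                     cell_state0 = NULL, iso = 0,
                                     s1_amp = NULL, n_s1 = 3, tol = 0.01,
                                     mult_range = c(0.25, 4),
                                     verbose = FALSE, ...) {
  if (is.null(cell_state0))
    cell_state0 <- pace_to_steady_state(iso, pcl = 1000,
                                        n_beats = 300)$final_state
  if (is.null(s1_amp))
    s1_amp <- 2 * capture_threshold(grid, cell_state0, iso = iso, ...)
  probes <- cable_probe_nodes(grid)
  cv_at <- function(mult) {
    g <- grid; g$sigma_l <- grid$sigma_l * mult
    g$sigma_t <- grid$sigma_t * mult
    s <- tissue_stimulus(region = 1:2, amplitude = s1_amp, onset = 0,
                         dur = 5, cycle_length = 1000, npulses = n_s1)
    r <- monodomain_simulate(g, s, duration = n_s1 * 1000, iso = iso,
                             init = cell_state0, probes = probes,
                             frame_dt = 100, ...)
    measure_cable_cv(r, window = c((n_s1 - 1) * 1000, n_s1 * 1000))
  }
  lo <- mult_range[1]; hi <- mult_range[2]
  cv_lo <- cv_at(lo); cv_hi <- cv_at(hi)
  if (is.na(cv_lo) || is.na(cv_hi) ||
      (cv_lo - target_cv) * (cv_hi - target_cv) > 0)
    stop("multiplier range does not bracket the target CV")
  mult <- NA; cv <- NA
  for (k in 1:40) {
    mult <- sqrt(lo * hi)
    cv <- cv_at(mult)
    if (abs(cv - target_cv) / target_cv < tol) break
    if (cv < target_cv) lo <- mult else hi <- mult
  }
  if (verbose)
    message(sprintf("conductivity multiplier %.4f -> CV %.2f cm/s", mult, cv))
  out <- grid
  out$sigma_l <- grid$sigma_l * mult
  out$sigma_t <- grid$sigma_t * mult
  attr(out, "multiplier") <- mult
  attr(out, "cv") <- cv
  attr(out, "s1_amp") <- s1_amp
  out
}

#' S1-S2 conduction-velocity restitution on a cable
#'
#' S1 train (default 20 beats at 1 Hz, 5 ms pulses) from the left edge,
#' then one premature S2 per coupling interval. The diastolic interval is
#' measured at the proximal probe (S2 activation time minus the S1 beat's
#' 90 percent repolarization time); CV of the S2 beat comes from
#' [measure_cable_cv()].
#'
#' @param grid Calibrated cable grid.
#' @param iso Uniform ISO (uM).
#' @param s2_cls S2 coupling intervals (ms from the last S1 stimulus).
#' @param n_s1 Number of S1 beats.
#' @param s1_cl S1 cycle length (ms).
#' @param s1_amp Stimulus amplitude (pA/pF); `NULL` uses the grid's
#'   calibration attribute or twice the capture threshold.
#' @param cell_state0 Optional pre-paced cell state at this ISO.
#' @param curves,mods See [integrate_cell()].
#' @param ... Passed to [monodomain_simulate()].
#' @return Data.frame (class `cv_restitution`) with `cl`, `di`, `cv`,
#'   `captured`.
#' @export
cv_restitution_cable <- function(grid, iso = 0,
                                 s2_cls = seq(1000, 250, by = -50),
                                 n_s1 = 20, s1_cl = 1000, s1_amp = NULL,
                                 cell_state0 = NULL,
                                 curves = dose_response_curves(),
                                 mods = bars_modifiers(), ...) {
  if (is.null(cell_state0))
    cell_state0 <- pace_to_steady_state(iso, pcl = s1_cl, n_beats = 300,
                                        curves = curves,
                                        mods = mods)$final_state
  if (is.null(s1_amp)) {
    s1_amp <- attr(grid, "s1_amp")
    if (is.null(s1_amp))
      s1_amp <- 2 * capture_threshold(grid, cell_state0, iso = iso,
                                      curves = curves, mods = mods, ...)
  }
  probes <- cable_probe_nodes(grid)
  # S1 conditioning up to (but not including) the last S1 stimulus
  s1 <- tissue_stimulus(region = 1:2, amplitude = s1_amp, onset = 0,
                        dur = 5, cycle_length = s1_cl, npulses = n_s1 - 1)
  cond <- monodomain_simulate(grid, s1, duration = (n_s1 - 1) * s1_cl,
                              iso = iso, init = cell_state0,
                              probes = probes, frame_dt = 100,
                              curves = curves, mods = mods, ...)
  state_s1 <- cond$final_states
  rows <- lapply(s2_cls, function(cl) {
    stim <- list(
      tissue_stimulus(region = 1:2, amplitude = s1_amp, onset = 0, dur = 5),
      tissue_stimulus(region = 1:2, amplitude = s1_amp, onset = cl, dur = 5))
    r <- monodomain_simulate(grid, stim, duration = cl + 500, iso = iso,
                             init = state_s1, probes = probes,
                             frame_dt = 100, curves = curves, mods = mods,
                             ...)
    t_rep <- repol_time_probe(r, probes[1], window = c(0, cl + 5))
    t_act <- activation_time_probe(r, probes[1], window = c(cl, cl + 200))
    cv <- suppressWarnings(measure_cable_cv(r, window = c(cl, cl + 400)))
    captured <- !is.na(t_act) && !is.na(cv)
    data.frame(cl = cl,
               di = if (captured && !is.na(t_rep)) t_act - t_rep else NA_real_,
               cv = if (captured) cv else NA_real_,
               captured = captured)
  })
  out <- do.call(rbind, rows)
  attr(out, "iso") <- iso
  class(out) <- c("cv_restitution", "data.frame")
  out
}

#' Induce a rotor with the cross-field S1-S2 protocol
#'
#' Plane waves are launched from the left edge (S1); a premature S2 over the
#' lower half of the sheet is delivered while the right half repolarizes,
#' producing a free wave end that curls into a rotor. When no S2 delay is
#' given, candidate delays are swept in steps of `s2_step` around the
#' repolarization time observed at a right-half probe during the
#' penultimate S1 beat, and the first delay producing sustained reentry is
#' kept.
#'
#' @param grid Sheet grid.
#' @param barsmap `bars_map` or `NULL` for a uniform sheet at `iso`.
#' @param iso Uniform ISO when `barsmap` is `NULL`.
#' @param init Per-node initial states; `NULL` computes
#'   [tissue_init_states()] at a 600 ms BCL.
#' @param n_s1 S1 beats (600 ms BCL).
#' @param s1_amp,s2_amp Stimulus amplitudes (pA/pF).
#' @param stim_dur Pulse width (ms).
#' @param s2_delays Candidate S2 delays (ms after the final S1 stimulus);
#'   `NULL` enables the automatic vulnerable-window search.
#' @param s2_step Search step (ms).
#' @param duration_post_s2 Recorded time after S2 (ms; the reference
#'   protocol uses 5000).
#' @param frame_dt Frame interval of the returned recording (ms).
#' @param probe_frac Relative x-position of the repolarization probe.
#' @param curves,mods See [integrate_cell()].
#' @param ... Passed to [monodomain_simulate()].
#' @return A `tissue_recording` of the post-S2 window (time 0 = S2 onset)
#'   with attributes `s2_delay` (ms after the final S1 stimulus) and
#'   `reentry` (logical). When no searched delay induces reentry the last
#'   recording is returned with `reentry = FALSE`.
#' @export
induce_rotor_s1s2 <- function(grid, barsmap = NULL, iso = 0, init = NULL,
                              n_s1 = 3, s1_amp = 40, s2_amp = 40,
                              stim_dur = 2, s2_delays = NULL, s2_step = 10,
                              duration_post_s2 = 5000, frame_dt = 2,
                              probe_frac = 0.75,
                              curves = dose_response_curves(),
                              mods = bars_modifiers(), ...) {
  if (grid$ny < 10) stop("rotor induction needs a 2-D sheet")
  if (is.null(init))
    init <- tissue_init_states(grid, barsmap, iso, curves = curves,
                               mods = mods)
  left_edge <- as.vector(outer(1:2, (0:(grid$ny - 1)) * grid$nx, `+`))
  lower_half <- which(rep(seq_len(grid$ny), each = grid$nx) <= grid$ny / 2)
  probe <- node_index(grid, round(probe_frac * grid$nx),
                      round(grid$ny / 2))
  s1_cl <- 600
  # conditioning: all but the final S1 beat
  s1 <- tissue_stimulus(region = left_edge, amplitude = s1_amp, onset = 0,
                        dur = stim_dur, cycle_length = s1_cl,
                        npulses = n_s1 - 1)
  cond <- monodomain_simulate(grid, s1, duration = (n_s1 - 1) * s1_cl,
                              barsmap = barsmap, iso = iso, init = init,
                              probes = probe, frame_dt = 100, trace_dt = 0.5,
                              curves = curves, mods = mods, ...)
  # repolarization timing of the penultimate beat at the right-half probe
  w0 <- (n_s1 - 2) * s1_cl
  t_rep <- repol_time_probe(cond, probe, window = c(w0, w0 + s1_cl)) - w0
  if (is.na(t_rep)) stop("no propagated beat at the repolarization probe")
  delays <- if (is.null(s2_delays))
    t_rep + seq(-2 * s2_step, 4 * s2_step, by = s2_step) else s2_delays
  delays <- delays[delays > 0]
  state_s1 <- cond$final_states
  check_ms <- 800
  rec <- NULL; reentry <- FALSE; used <- NA_real_
  for (d in delays) {
    # final S1 beat plus S2 at delay d, stop at S2 onset
    pre <- monodomain_simulate(grid, list(
      tissue_stimulus(region = left_edge, amplitude = s1_amp, onset = 0,
                      dur = stim_dur)),
      duration = d, barsmap = barsmap, iso = iso, init = state_s1,
      probes = probe, frame_dt = max(d, 1), curves = curves, mods = mods,
      ...)
    # probe window: short confirmation segment, then the remainder
    seg1 <- monodomain_simulate(grid, list(
      tissue_stimulus(region = lower_half, amplitude = s2_amp, onset = 0,
                      dur = stim_dur)),
      duration = min(check_ms, duration_post_s2), barsmap = barsmap,
      iso = iso, init = pre$final_states, probes = probe,
      frame_dt = frame_dt, curves = curves, mods = mods, ...)
    nt <- nrow(seg1$frames)
    tail_idx <- which(seg1$frame_time >= max(seg1$frame_time) - 100)
    active <- max(seg1$frames[tail_idx, , drop = FALSE]) > -40
    if (active || d == delays[length(delays)]) {
      if (duration_post_s2 > check_ms) {
        seg2 <- monodomain_simulate(grid, list(), duration =
          duration_post_s2 - check_ms, barsmap = barsmap, iso = iso,
          init = seg1$final_states, probes = probe, frame_dt = frame_dt,
          curves = curves, mods = mods, ...)
        rec <- seg1
        rec$frames <- rbind(seg1$frames,
                            seg2$frames[-1, , drop = FALSE])
        rec$frame_time <- c(seg1$frame_time,
                            seg2$frame_time[-1] + max(seg1$frame_time))
        rec$final_states <- seg2$final_states
        rec$n_activations <- seg1$n_activations + seg2$n_activations
      } else rec <- seg1
      tail2 <- which(rec$frame_time >= max(rec$frame_time) - 200)
      reentry <- max(rec$frames[tail2, , drop = FALSE]) > -40
      used <- d
      if (reentry) break
    }
  }
  if (!reentry)
    message("no sustained reentry induced over the searched S2 delays")
  attr(rec, "s2_delay") <- used
  attr(rec, "reentry") <- reentry
  rec
}
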