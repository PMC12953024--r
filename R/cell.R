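#' Initial ionic state of the myocyte
#'
#' Returns the TT2 resting initial conditions with the phosphorylated gate
#' copies initialised equal to their non-phosphorylated counterparts
#' (required so that behaviour at ISO = 0 is independent of the modifiers).
#'
#' @return Named numeric vector of the 26 state variables, class
#'   `ionic_state`: membrane potential `Vm` (mV), intracellular
#'   concentrations (mM), 13 baseline gates plus fCaSS and Rbar, and the
#'   phosphorylated copies `h_P, j_P, d_P, f_P, f2_P, xs_P, Rbar_P`.
#' @export
cell_state <- function() {
  y <- cpp_default_state()
  names(y) <- cpp_state_names()
  class(y) <- "ionic_state"
  y
}

as_state <- function(state) {
  if (is.null(state)) state <- cell_state()
  s <- as.numeric(state)
  if (length(s) != 26L) stop("an ionic state has 26 components")
  s
}

as_alpha <- function(profile) {
  a <- as.numeric(profile)
  if (length(a) != 9L) stop("a phosphorylation profile has 9 components")
  if (any(a < 0 | a > 1)) stop("phosphorylation fractions must be in [0, 1]")
  a
}

#' Membrane currents and fluxes for a given state
#'
#' Evaluates every target current in its non-phosphorylated (`_NP`) and
#' phosphorylated (`_P`) form together with the mixed net current
#' (`I_net = I_NP + alpha (I_P - I_NP)`), the unmodified TT2 currents, and
#' the total ionic current `Itot` (pA/pF; SR fluxes in mM/ms).
#'
#' @param state Ionic state vector (see [cell_state()]).
#' @param profile Phosphorylation fractions, see [phosphorylation_profile()].
#' @param mods Modifier set, see [bars_modifiers()].
#' @param bars If `FALSE` all dual-population machinery is bypassed
#'   (baseline-only build used for equivalence checks).
#' @return Named numeric vector of currents.
#' @examples
#' cs <- membrane_currents(cell_state(), phosphorylation_profile(1))
#' cs["INa"]
#' @export
membrane_currents <- function(state, profile = phosphorylation_profile(0),
                              mods = bars_modifiers(), bars = TRUE) {
  out <- cpp_rhs(as_state(state), as_alpha(profile), mods, bars, 0)
  cur <- out$currents
  names(cur) <- cpp_current_names()
  if (any(!is.finite(cur))) {
    bad <- names(cur)[!is.finite(cur)]
    stop("numerical blow-up: non-finite current(s): ",
         paste(bad, collapse = ", "))
  }
  cur
}

#' Time derivative of the ionic state
#'
#' Right-hand side of the cell ODE system:
#' `dVm/dt = -(sum I_ion - I_stim) / C_m` with currents in pA/pF and
#' `C_m = 1 uF/cm^2`, Hodgkin-Huxley gate kinetics (phosphorylated copies
#' with shifted steady-state curves and scaled time constants), and
#' concentration balance equations.
#'
#' @inheritParams membrane_currents
#' @param istim Stimulus current density (pA/pF), positive depolarising.
#' @return Named numeric vector of 26 derivatives (per ms).
#' @export
state_derivative <- function(state, profile = phosphorylation_profile(0),
                             mods = bars_modifiers(), istim = 0,
                             bars = TRUE) {
  out <- cpp_rhs(as_state(state), as_alpha(profile), mods, bars, istim)
  d <- out$deriv
  names(d) <- cpp_state_names()
  if (any(!is.finite(d))) stop("numerical blow-up: non-finite derivative")
  d
}

make_cell_trace <- function(raw, iso, dt, extra = list()) {
  st <- raw$states; colnames(st) <- cpp_state_names()
  cu <- raw$currents; colnames(cu) <- cpp_current_names()
  tr <- data.frame(time_ms = raw$time, st, cu, check.names = FALSE)
  attr(tr, "iso") <- iso
  attr(tr, "dt") <- dt
  attr(tr, "final_state") <- raw$final_state
  for (n in names(extra)) attr(tr, n) <- extra[[n]]
  class(tr) <- c("cell_trace", "data.frame")
  tr
}

#' Integrate the single cell forward in time
#'
#' Fixed-step integration: Rush-Larsen exponential updates for
#' Hodgkin-Huxley gates (with voltage-dependent rates tabulated at 0.02 mV
#' resolution), exact exponential updates for the linear RyR adaptation
#' variables, and forward Euler for concentrations and Vm.
#'
#' @param state0 Initial state (default [cell_state()]).
#' @param iso ISO concentration (uM).
#' @param duration Total time (ms).
#' @param dt Time step (ms), at most 0.02 for the default scheme.
#' @param stim_onsets Stimulus onset times (ms); empty for none.
#' @param stim_amp Stimulus amplitude (pA/pF; 60 uA/cm^2 with
#'   Cm = 1 uF/cm^2 is 60 pA/pF).
#' @param stim_dur Stimulus pulse width (ms).
#' @param record_dt Sampling interval of the returned trace (ms).
#' @param curves Dose-response curves, see [dose_response_curves()].
#' @param mods Modifiers, see [bars_modifiers()].
#' @param bars If `FALSE`, run the baseline-only build.
#' @return A `cell_trace` data.frame: `time_ms`, the 26 state variables and
#'   all current columns; attributes hold `iso`, `dt` and the final state.
#' @examples
#' tr <- integrate_cell(duration = 50, stim_onsets = 5)
#' max(tr$Vm)
#' @export
integrate_cell <- function(state0 = NULL, iso = 0, duration, dt = 0.02,
                           stim_onsets = numeric(0), stim_amp = 60,
                           stim_dur = 1, record_dt = 0.5,
                           curves = dose_response_curves(),
                           mods = bars_modifiers(), bars = TRUE) {
  stopifnot(duration > 0, dt > 0)
  if (dt > 0.02 + 1e-12)
    stop("dt must be <= 0.02 ms for the default explicit scheme")
  a <- as_alpha(phosphorylation_profile(iso, curves))
  raw <- cpp_integrate(as_state(state0), a, mods, bars, dt, duration,
                       as.numeric(stim_onsets), stim_amp, stim_dur, record_dt)
  make_cell_trace(raw, iso, dt)
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %d samples over %.1f ms (ISO = %g uM)\n",
              nrow(x), max(x$time_ms), attr(x, "iso")))
  cat(sprintf("  Vm range [%.1f, %.1f] mV; Cai range [%.2e, %.2e] mM\n",
              min(x$Vm), max(x$Vm), min(x$Cai), max(x$Cai)))
  invisible(x)
}

#' @export
plot.cell_trace <- function(x, what = c("Vm", "Cai"), ...) {
  op <- par(mfrow = c(length(what), 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  for (w in what)
    plot(x$time_ms, x[[w]], type = "l", xlab = "time (ms)", ylab = w, ...)
  invisible(x)
}
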