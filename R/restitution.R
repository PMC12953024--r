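#' Dynamic APD restitution protocol
#'
#' Paces the cell at successively shorter cycle lengths (default 2000 ms
#' decreasing in 100 ms steps) until loss of capture. Each cycle length is
#' run to steady state (up to `n_beats`, with convergence-based early exit)
#' starting from the final state of the previous cycle length; APD90 is
#' taken from the last beat. The diastolic interval of each entry is
#' `pcl - apd90` of the preceding beat at that cycle length.
#'
#' @param iso ISO concentration (uM).
#' @param pcl_start Longest pacing cycle length (ms).
#' @param pcl_step Decrement per stage (ms, negative).
#' @param pcl_min Shortest cycle length attempted (ms).
#' @param n_beats Maximum beats per stage.
#' @param amplitude,pulse_ms,dt,curves,mods See [pace_to_steady_state()].
#' @return Data.frame (class `restitution_curve`) with `pcl`, `apd90`,
#'   `di`, `captured`; rows after loss of capture are flagged and the
#'   protocol stops there.
#' @export
apd_restitution <- function(iso = 0, pcl_start = 2000, pcl_step = -100,
                            pcl_min = 100, n_beats = 1000, amplitude = 60,
                            pulse_ms = 1, dt = 0.02,
                            curves = dose_response_curves(),
                            mods = bars_modifiers()) {
  stopifnot(pcl_step < 0, pcl_start > 0)
  pcls <- seq(pcl_start, pcl_min, by = pcl_step)
  state <- cell_state()
  rows <- list()
  for (pcl in pcls) {
    p <- suppressWarnings(
      pace_to_steady_state(iso, pcl = pcl, n_beats = n_beats,
                           amplitude = amplitude, pulse_ms = pulse_ms,
                           dt = dt, state0 = state, curves = curves,
                           mods = mods))
    nb <- nrow(p$beats)
    last <- p$beats[nb, ]
    captured <- isTRUE(last$captured == 1L) && is.finite(last$apd90)
    prev_apd <- if (nb > 1) p$beats$apd90[nb - 1] else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      pcl = pcl,
      apd90 = if (captured) last$apd90 else NA_real_,
      di = if (captured && is.finite(prev_apd)) pcl - prev_apd else NA_real_,
      captured = captured)
    if (!captured) break
    state <- p$final_state
  }
  out <- do.call(rbind, rows)
  attr(out, "iso") <- iso
  class(out) <- c("restitution_curve", "data.frame")
  out
}

#' @export
plot.restitution_curve <- function(x, ...) {
  ok <- x$captured
  plot(x$pcl[ok], x$apd90[ok], type = "b", xlab = "PCL (ms)",
       ylab = "APD90 (ms)", ...)
  invisible(x)
}
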