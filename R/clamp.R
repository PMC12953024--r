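#' Default voltage-clamp protocols per channel
#'
#' INa: 300 ms steps from -80 to +20 mV, holding -90 mV (the printed
#' holding of 0 mV would leave the channels fully inactivated and is
#' available by overriding `holding_vm`). ICaL: 500 ms steps from -40 to
#' +60 mV, holding -90 mV. IKs: 3000 ms steps from -40 to +60 mV, holding
#' -40 mV.
#'
#' @param channel One of "INa", "ICaL", "IKs".
#' @return List with `holding_vm`, `step_vms`, `step_ms`.
#' @export
clamp_protocol <- function(channel = c("INa", "ICaL", "IKs")) {
  channel <- match.arg(channel)
  switch(channel,
    INa  = list(holding_vm = -90, step_vms = seq(-80, 20, by = 10),
                step_ms = 300),
    ICaL = list(holding_vm = -90, step_vms = seq(-40, 60, by = 5),
                step_ms = 500),
    IKs  = list(holding_vm = -40, step_vms = seq(-40, 60, by = 5),
                step_ms = 3000))
}

#' Virtual voltage-clamp I-V experiment
#'
#' Vm is clamped to a holding potential (5 s of conditioning after an
#' initial 1 Hz steady-state run at the same ISO), then stepped; the peak
#' absolute net current of the selected channel is recorded per step. The
#' state is re-set to the post-holding state before every step, so steps
#' are independent.
#'
#' @param channel "INa", "ICaL" or "IKs".
#' @param iso ISO concentration (uM).
#' @param protocol A list as returned by [clamp_protocol()]; fields can be
#'   overridden individually via `...` style modification before the call.
#' @param normalize If `TRUE`, additionally run the protocol at ISO = 0 and
#'   return the ratio curve (`peak / peak_baseline`).
#' @param state0 Optional pre-paced state; when `NULL` a 1 Hz steady-state
#'   run (up to `n_precondition_beats`) is performed first.
#' @param n_precondition_beats Beats of 1 Hz preconditioning.
#' @param dt Integration step (ms).
#' @param curves,mods See [integrate_cell()].
#' @return Data.frame (class `iv_curve`) with columns `step_vm`, `peak`
#'   (signed peak current, pA/pF) and, when `normalize`, `peak_baseline`
#'   and `ratio`.
#' @export
voltage_clamp_iv <- function(channel = c("INa", "ICaL", "IKs"), iso = 0,
                             protocol = clamp_protocol(channel),
                             normalize = FALSE, state0 = NULL,
                             n_precondition_beats = 200, dt = 0.02,
                             curves = dose_response_curves(),
                             mods = bars_modifiers()) {
  channel <- match.arg(channel)
  stopifnot(protocol$step_ms > 0, length(protocol$step_vms) > 0)
  a <- as_alpha(phosphorylation_profile(iso, curves))
  if (is.null(state0)) {
    p <- pace_to_steady_state(iso, pcl = 1000,
                              n_beats = n_precondition_beats,
                              dt = dt, curves = curves, mods = mods)
    state0 <- p$final_state
  }
  # 5 s conditioning at the holding potential
  hold <- cpp_clamp(as_state(state0), a, mods, TRUE,
                    seg_vm = protocol$holding_vm, seg_ms = 5000,
                    dt = dt, record_dt = 1000)
  y0 <- hold$final_state
  sgn <- if (channel %in% c("INa", "ICaL")) -1 else 1
  cn <- cpp_current_names()
  peaks <- vapply(protocol$step_vms, function(vstep) {
    r <- cpp_clamp(y0, a, mods, TRUE,
                   seg_vm = vstep, seg_ms = protocol$step_ms,
                   dt = dt, record_dt = max(dt, 0.1))
    cur <- r$currents[, which(cn == channel)]
    if (sgn < 0) min(cur) else max(cur)
  }, numeric(1))
  out <- data.frame(step_vm = protocol$step_vms, peak = peaks)
  if (normalize) {
    base <- voltage_clamp_iv(channel, iso = 0, protocol = protocol,
                             normalize = FALSE,
                             state0 = if (iso == 0) state0 else NULL,
                             n_precondition_beats = n_precondition_beats,
                             dt = dt, curves = curves, mods = mods)
    out$peak_baseline <- base$peak
    out$ratio <- out$peak / base$peak
  }
  attr(out, "channel") <- channel
  attr(out, "iso") <- iso
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Steady-state Na+ channel availability
#'
#' Availability (the h*j product at steady state) after a 300 ms
#' conditioning step, for conditioning potentials in `vms`.
#'
#' @param vms Conditioning potentials (mV).
#' @param iso ISO concentration (uM).
#' @param state0 Optional starting state.
#' @param dt Integration step (ms).
#' @param curves,mods See [integrate_cell()].
#' @return Data.frame with `vm`, `availability` (mixed across populations).
#' @export
na_availability <- function(vms = seq(-120, -80, by = 5), iso = 0,
                            state0 = NULL, dt = 0.02,
                            curves = dose_response_curves(),
                            mods = bars_modifiers()) {
  a <- as_alpha(phosphorylation_profile(iso, curves))
  y0 <- as_state(state0)
  av <- vapply(vms, function(v) {
    r <- cpp_clamp(y0, a, mods, TRUE, seg_vm = v, seg_ms = 300,
                   dt = dt, record_dt = 300)
    y <- r$final_state
    nm <- cpp_state_names()
    hj_np <- y[nm == "h"] * y[nm == "j"]
    hj_p <- y[nm == "h_P"] * y[nm == "j_P"]
    (1 - a[1]) * hj_np + a[1] * hj_p
  }, numeric(1))
  data.frame(vm = vms, availability = av)
}
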