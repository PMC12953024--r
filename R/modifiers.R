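#' Scale factors and voltage shifts defining the phosphorylated populations
#'
#' Each phosphorylated (P) channel population is the baseline TT2 formulation
#' with these modifiers applied. Shifts are in mV and follow the convention
#' that a negative shift moves a gating curve leftward (the P curve at
#' potential V equals the baseline curve at V - shift).
#'
#' Defaults:
#' \itemize{
#'  \item INa: conductance x1.7 (`gNa_scale`), inactivation gates h and j
#'    shifted -5 mV (`h_shift`).
#'  \item ICaL: conductance x3 (`gCaL_scale`); d, f, f2 gates shifted -10 mV
#'    (`dff2_shift`); activation 1.25x faster near threshold potentials
#'    (`dtau_speedup`, V < 0 mV) and inactivation 1.6x slower at strongly
#'    positive potentials (`ftau_slowdown`, V > +20 mV), blended smoothly
#'    over a 5 mV sigmoid.
#'  \item IKs: conductance x2.5 (`gKs_scale`), activation gate xs shifted
#'    -5 mV (`xs_shift`), activation rate multiplied by `xs_rate_scale`.
#'    The rate factor is a calibration parameter (default 2.0), set once
#'    together with the dose-response saturation levels against the
#'    steady-state 1 Hz validation bundle (see the methods vignette).
#'  \item INaK: intracellular Na+ half-saturation constant x0.7
#'    (`kmNa_scale`).
#'  \item IpK: current x2 (`gpK_scale`), activation shifted +10 mV
#'    (`pK_shift`).
#'  \item RyR release: conductance x1.6 (`gRel_scale`), channel opening rate
#'    k1 x1.4 (`ryr_open_scale`), adaptation closing rate k2 x1.8
#'    (`ryr_close_scale`); the P population carries its own adaptation
#'    variable Rbar_P.
#'  \item SERCA uptake: half-saturation constant x0.85 (`kUp_scale`) and
#'    maximal uptake rate scaled by `vmaxUp_scale`. The Vmax factor is a
#'    calibration parameter: baseline TT2 uptake is nearly saturated at
#'    systolic Ca2+, so the reported ~1.9-fold uptake increase under
#'    phosphorylated phospholamban is unreachable through the
#'    half-saturation change alone; the default (2.0) was set once against
#'    that uptake fold change.
#'  \item Subspace-to-cytosol transfer: x2.1 (`vXfer_scale`).
#'  \item Cytosolic Ca2+ buffering: half-saturation constant x1.7
#'    (`kBufc_scale`), mixed algebraically as
#'    (1 - alpha) Kbufc + alpha 1.7 Kbufc.
#' }
#'
#' The SR leak flux is never modified. `dff2_shift = -5` and applying the
#' IKs shift differently are available as overrides for sensitivity studies.
#'
#' @param ... Named overrides of any default listed above.
#' @return Named list of modifiers, class `bars_modifiers`.
#' @examples
#' bars_modifiers()
#' bars_modifiers(gCaL_scale = 2.5, dff2_shift = -5)
#' @export
bars_modifiers <- function(...) {
  m <- list(
    gNa_scale = 1.7, h_shift = -5, gCaL_scale = 3.0, dff2_shift = -10,
    dtau_speedup = 1.25, ftau_slowdown = 1.6,
    gKs_scale = 2.5, xs_shift = -5, xs_rate_scale = 2.0,
    kmNa_scale = 0.7, gpK_scale = 2.0, pK_shift = 10,
    gRel_scale = 1.6, ryr_open_scale = 1.4, ryr_close_scale = 1.8,
    vXfer_scale = 2.1, kUp_scale = 0.85, vmaxUp_scale = 2.0,
    kBufc_scale = 1.7)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(m))
    if (length(bad)) stop("unknown modifier(s): ", paste(bad, collapse = ", "))
    m[names(ov)] <- ov
  }
  sc <- grep("_scale$|speedup|slowdown", names(m), value = TRUE)
  if (any(unlist(m[sc]) <= 0)) stop("all scale factors must be > 0")
  class(m) <- "bars_modifiers"
  m
}

#' @export
print.bars_modifiers <- function(x, ...) {
  cat("Phosphorylated-population modifiers:\n")
  for (n in names(x)) cat(sprintf("  %-16s %g\n", n, x[[n]]))
  invisible(x)
}
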