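#' Zero-phase band-pass filter for action-potential signals
#'
#' Fourth-order Butterworth band-pass (0.1 to 15 Hz by default) applied
#' forward-backward (zero phase distortion, as required for a meaningful
#' Hilbert phase). The per-node mean is removed first; the output is
#' mean-free.
#'
#' @param x Numeric vector, or matrix with one signal per column.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges (Hz).
#' @param order Butterworth order of each (low/high-pass) section.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, fs, low = 0.1, high = 15, order = 4) {
  stopifnot(fs > 2 * high)
  if (is.matrix(x)) {
    if (nrow(x) < 3 * order)
      stop("signal shorter than the filter transient")
    return(apply(x, 2, bandpass, fs = fs, low = low, high = high,
                 order = order))
  }
  if (length(x) < 3 * order) stop("signal shorter than the filter transient")
  x <- x - mean(x)
  # cascade of a second-order high-pass and a fourth-order low-pass,
  # each applied forward-backward: numerically robust for the very low
  # lower corner relative to fs, with negligible passband droop
  hp <- signal::butter(max(1, order %/% 2), low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  y - mean(y)
}

#' Analytic signal via the discrete Hilbert transform
#'
#' @param x Zero-mean numeric vector.
#' @return Complex vector `x + i H[x]`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  fft(X * w, inverse = TRUE) / n
}

#' Instantaneous phase of a filtered signal
#'
#' theta(t) = atan2(Im h(t), Re h(t)) with h the analytic signal from the
#' discrete Hilbert transform; theta lies in (-pi, pi]. A rotor wavefront
#' corresponds to theta = -pi/2 under this convention.
#'
#' @param x Zero-mean numeric vector (or matrix, one signal per column).
#' @param amplitude_floor Minimum analytic-signal amplitude below which the
#'   phase is undefined and returned as `NA`.
#' @return Phase series (radians), same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 0.002)
#' th <- instantaneous_phase(cos(2 * pi * 5 * t))
#' @export
instantaneous_phase <- function(x, amplitude_floor = 1e-12) {
  if (is.matrix(x))
    return(apply(x, 2, instantaneous_phase,
                 amplitude_floor = amplitude_floor))
  if (all(x == 0)) return(rep(NA_real_, length(x)))
  h <- analytic_signal(x)
  th <- atan2(Im(h), Re(h))
  th[Mod(h) < amplitude_floor] <- NA_real_
  th
}

#' Phase maps of a tissue recording
#'
#' Band-pass filters every node's Vm trace, takes the Hilbert phase, and
#' returns per-frame phase maps.
#'
#' @param recording A `tissue_recording` (frame interval at most 2 ms).
#' @param low,high Band edges (Hz).
#' @return A `phase_frames` object: matrix time x node of phases plus grid
#'   metadata (wavefront convention theta = -pi/2 recorded in the
#'   `wavefront` attribute).
#' @export
phase_frames <- function(recording, low = 0.1, high = 15) {
  dt_s <- diff(recording$frame_time[1:2]) / 1000
  if (dt_s > 0.002 + 1e-9)
    stop("phase analysis needs a frame interval of at most 2 ms")
  fs <- 1 / dt_s
  filt <- bandpass(recording$frames, fs = fs, low = low, high = high)
  ph <- instantaneous_phase(filt)
  structure(list(phase = ph, time = recording$frame_time,
                 nx = recording$grid$nx, ny = recording$grid$ny,
                 dx_cm = recording$grid$dx_cm),
            class = "phase_frames", wavefront = -pi / 2)
}
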