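wrap_phase <- function(d) {
  (d + pi) %% (2 * pi) - pi
}

#' Winding numbers of every 2 x 2 plaquette of a phase map
#'
#' Brute-force closed-loop phase integral around each elementary plaquette;
#' +1 / -1 where the phase winds by +/- 2 pi. This is the normative
#' reference detector used by the tests.
#'
#' @param theta Phase matrix (ny rows, nx columns).
#' @return Integer matrix (ny - 1) x (nx - 1) of winding numbers.
#' @export
plaquette_winding <- function(theta) {
  ny <- nrow(theta); nx <- ncol(theta)
  t00 <- theta[-ny, -nx]; t10 <- theta[-ny, -1]
  t11 <- theta[-1, -1];  t01 <- theta[-1, -nx]
  s <- wrap_phase(t10 - t00) + wrap_phase(t11 - t10) +
       wrap_phase(t01 - t11) + wrap_phase(t00 - t01)
  w <- round(s / (2 * pi))
  w[is.na(w)] <- 0L
  w
}

# plane-fit gradients of z over a window; returns c(gx, gy)
plane_gradient <- function(z) {
  ny <- nrow(z); nx <- ncol(z)
  xs <- rep(seq_len(nx), each = ny) - (nx + 1) / 2
  ys <- rep(seq_len(ny), times = nx) - (ny + 1) / 2
  zz <- as.vector(z)
  ok <- is.finite(zz)
  if (sum(ok) < 6) return(c(NA_real_, NA_real_))
  gx <- sum(xs[ok] * zz[ok]) / sum(xs[ok]^2)
  gy <- sum(ys[ok] * zz[ok]) / sum(ys[ok]^2)
  c(gx, gy)
}

#' Detect phase singularities in one phase map
#'
#' Candidate sites are plaquettes whose closed-loop phase integral is
#' +/- 2 pi; each candidate is then confirmed by local plane regressions of
#' sin(theta) and cos(theta) over a surrounding window (10 x 10 nodes by
#' default): the site is accepted when the fitted gradients circulate,
#' i.e. the cross product grad cos x grad sin has the same sign as the
#' winding number. Chirality is the sign of the winding number. Detections
#' within `edge_margin` nodes of the boundary are excluded.
#'
#' @param theta Phase map: matrix ny x nx, or a `phase_frames` object plus
#'   `frame` index.
#' @param dx_cm Element edge (cm) for mm coordinates.
#' @param frame Frame index when `theta` is a `phase_frames` object.
#' @param window Regression window size in nodes.
#' @param edge_margin Boundary exclusion margin in nodes.
#' @return Data.frame with `x_mm`, `y_mm` (plaquette-centre coordinates),
#'   `ix`, `iy` (plaquette indices) and `chirality` (+/- 1).
#' @export
detect_phase_singularities <- function(theta, dx_cm = 0.04, frame = NULL,
                                       window = 10, edge_margin = 5) {
  if (inherits(theta, "phase_frames")) {
    pf <- theta
    dx_cm <- pf$dx_cm
    theta <- matrix(pf$phase[frame, ], nrow = pf$ny, ncol = pf$nx,
                    byrow = TRUE)
  }
  w <- plaquette_winding(theta)
  idx <- which(w != 0, arr.ind = TRUE)
  out <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                    ix = integer(0), iy = integer(0), chirality = integer(0))
  if (!nrow(idx)) return(out)
  ny <- nrow(theta); nx <- ncol(theta)
  half <- window %/% 2
  keep <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    iy <- idx[k, 1]; ix <- idx[k, 2]
    if (ix <= edge_margin || iy <= edge_margin ||
        ix > nx - edge_margin || iy > ny - edge_margin) next
    ylo <- max(1, iy - half + 1); yhi <- min(ny, iy + half)
    xlo <- max(1, ix - half + 1); xhi <- min(nx, ix + half)
    win <- theta[ylo:yhi, xlo:xhi]
    gs <- plane_gradient(sin(win))
    gc <- plane_gradient(cos(win))
    cross <- gc[1] * gs[2] - gc[2] * gs[1]
    keep[k] <- is.finite(cross) &&
      (abs(cross) < 1e-12 || sign(cross) == sign(w[iy, ix]))
  }
  idx <- idx[keep, , drop = FALSE]
  if (!nrow(idx)) return(out)
  data.frame(
    x_mm = (idx[, 2] + 0.5 - 0.5) * dx_cm * 10,  # plaquette centre
    y_mm = (idx[, 1] + 0.5 - 0.5) * dx_cm * 10,
    ix = idx[, 2], iy = idx[, 1],
    chirality = as.integer(w[idx]))
}

#' Track phase singularities across frames
#'
#' Greedy nearest-neighbour linking: each detection is attached to the
#' nearest active track of matching chirality within `link_radius`;
#' unmatched detections open new tracks; tracks missing for more than
#' `max_gap` frames are closed.
#'
#' @param frames A `phase_frames` object, or a list of per-frame detection
#'   data.frames (as from [detect_phase_singularities()]).
#' @param times Frame times (ms), required when `frames` is a list.
#' @param link_radius Maximum per-frame displacement (mm).
#' @param max_gap Frames a track may be missing before it is closed.
#' @param ... Passed to [detect_phase_singularities()].
#' @return A `ps_tracks` object: list of data.frames (`time`, `x_mm`,
#'   `y_mm`, `chirality`) with a `lifetime` attribute each (ms).
#' @export
track_singularities <- function(frames, times = NULL, link_radius = 4,
                                max_gap = 2, ...) {
  if (inherits(frames, "phase_frames")) {
    pf <- frames
    times <- pf$time
    dets <- lapply(seq_along(times), function(i)
      detect_phase_singularities(pf, frame = i, ...))
  } else dets <- frames
  stopifnot(length(dets) == length(times))
  active <- list()   # each: list(rows = list of df rows, last_seen = frame)
  done <- list()
  for (fi in seq_along(dets)) {
    d <- dets[[fi]]
    used <- rep(FALSE, nrow(d))
    # close stale tracks
    if (length(active)) {
      stale <- vapply(active, function(tr) fi - tr$last_seen > max_gap + 1,
                      logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    if (length(active) && nrow(d)) {
      # match tracks in order of distance
      for (ti in seq_along(active)) {
        tr <- active[[ti]]
        last <- tr$rows[[length(tr$rows)]]
        cand <- which(!used & d$chirality == last$chirality)
        if (!length(cand)) next
        dist <- sqrt((d$x_mm[cand] - last$x_mm)^2 +
                     (d$y_mm[cand] - last$y_mm)^2)
        j <- cand[which.min(dist)]
        if (min(dist) <= link_radius * (fi - tr$last_seen)) {
          active[[ti]]$rows <- c(tr$rows, list(
            data.frame(time = times[fi], x_mm = d$x_mm[j], y_mm = d$y_mm[j],
                       chirality = d$chirality[j])))
          active[[ti]]$last_seen <- fi
          used[j] <- TRUE
        }
      }
    }
    if (any(!used)) {
      for (j in which(!used)) {
        active[[length(active) + 1]] <- list(
          rows = list(data.frame(time = times[fi], x_mm = d$x_mm[j],
                                 y_mm = d$y_mm[j],
                                 chirality = d$chirality[j])),
          last_seen = fi)
      }
    }
  }
  done <- c(done, active)
  tracks <- lapply(done, function(tr) {
    df <- do.call(rbind, tr$rows)
    attr(df, "lifetime") <- max(df$time) - min(df$time)
    df
  })
  # order by lifetime, longest first
  lt <- vapply(tracks, attr, numeric(1), "lifetime")
  tracks <- tracks[order(-lt)]
  class(tracks) <- "ps_tracks"
  tracks
}

#' @export
print.ps_tracks <- function(x, ...) {
  lt <- vapply(x, attr, numeric(1), "lifetime")
  cat(sprintf("<ps_tracks> %d tracks; lifetimes (ms): %s\n", length(x),
              paste(round(sort(lt, decreasing = TRUE)[seq_len(min(5, length(lt)))]),
                    collapse = ", ")))
  invisible(x)
}

track_lifetime <- function(track) attr(track, "lifetime")

#' Rotor angular speed from a fixed probe
#'
#' Takes a probe node a fixed distance (4 mm by default, a typical mapping
#' catheter inter-electrode spacing) from the track's median position,
#' band-passes and Hilbert-transforms its Vm signal, and counts full 2 pi
#' revolutions of the unwrapped phase over the analysis window.
#'
#' @param track One track from [track_singularities()].
#' @param recording The `tissue_recording` the track came from.
#' @param probe_distance Probe offset from the median PS position (mm).
#' @param window Analysis window (ms); the reference protocol uses at least
#'   4000.
#' @return Angular speed in Hz.
#' @export
angular_speed <- function(track, recording, probe_distance = 4,
                          window = 4000) {
  if (track_lifetime(track) < window)
    warning(sprintf("track lifetime %.0f ms shorter than window %.0f ms",
                    track_lifetime(track), window))
  g <- recording$grid
  cx <- median(track$x_mm); cy <- median(track$y_mm)
  px <- cx + probe_distance
  ix <- round(px / (g$dx_cm * 10)); iy <- round(cy / (g$dx_cm * 10))
  if (ix > g$nx - 3 || ix < 3) {
    warning("probe outside grid; using nearest interior node")
    ix <- min(max(ix, 3), g$nx - 3)
  }
  iy <- min(max(iy, 3), g$ny - 3)
  node <- node_index(g, ix, iy)
  tm <- recording$frame_time
  t0 <- min(track$time)
  sel <- tm >= t0 & tm <= t0 + window
  vm <- recording$frames[sel, node]
  fs <- 1000 / diff(tm[1:2])
  th <- instantaneous_phase(bandpass(vm, fs = fs))
  un <- unwrap_phase(th)
  span <- (tail(tm[sel], 1) - tm[sel][1]) / 1000
  revolutions <- abs(un[length(un)] - un[1]) / (2 * pi)
  revolutions / span
}

unwrap_phase <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(th[1], th[1] + cumsum(d))
}

#' Rotor localization area
#'
#' Total substrate area over which the phase singularity was present during
#' the window: the count of distinct grid elements visited by the track
#' times the element area (0.16 mm^2 at 400 um).
#'
#' @param track One track from [track_singularities()].
#' @param window Analysis window from track start (ms).
#' @param dx_mm Element edge (mm).
#' @return Area in mm^2. Tracks shorter than the window are evaluated over
#'   their lifetime with a warning and a `short_track` attribute.
#' @export
localization_area <- function(track, window = 4000, dx_mm = 0.4) {
  short <- track_lifetime(track) < window
  if (short)
    warning(sprintf("track lifetime %.0f ms shorter than window %.0f ms",
                    track_lifetime(track), window))
  sel <- track$time <= min(track$time) + window
  cells <- unique(paste(floor(track$x_mm[sel] / dx_mm),
                        floor(track$y_mm[sel] / dx_mm)))
  structure(length(cells) * dx_mm^2, short_track = short)
}

#' Mean number of simultaneous wavelets
#'
#' Mean count of simultaneously alive tracks with lifetime at least
#' `min_lifetime`, averaged over the analysis window.
#'
#' @param tracks A `ps_tracks` object from one recording.
#' @param times Frame times over which to average (ms); defaults to the
#'   union of all track times.
#' @param min_lifetime Minimum lifetime for a track to count (ms).
#' @return Mean simultaneous count.
#' @export
count_wavelets <- function(tracks, times = NULL, min_lifetime = 100) {
  keep <- Filter(function(tr) track_lifetime(tr) >= min_lifetime, tracks)
  if (!length(keep)) return(0)
  if (is.null(times))
    times <- sort(unique(unlist(lapply(keep, `[[`, "time"))))
  counts <- vapply(times, function(t)
    sum(vapply(keep, function(tr)
      t >= min(tr$time) && t <= max(tr$time), logical(1))), numeric(1))
  mean(counts)
}
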