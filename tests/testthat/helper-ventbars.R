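# shared fixtures and independent oracles

# synthetic phase field with singularities at (xk, yk) of chirality ck
# (node units); theta = sum of signed polar angles, wrapped to (-pi, pi]
synth_phase_field <- function(nx, ny, xs, ys, ch, twist = 0) {
  gx <- matrix(rep(seq_len(nx), each = ny), nrow = ny)
  gy <- matrix(rep(seq_len(ny), times = nx), nrow = ny)
  th <- matrix(0, ny, nx)
  for (k in seq_along(xs)) {
    r <- sqrt((gx - xs[k])^2 + (gy - ys[k])^2)
    th <- th + ch[k] * (atan2(gy - ys[k], gx - xs[k]) + twist * r)
  }
  atan2(sin(th), cos(th))
}

# independent brute-force winding-number oracle: explicit loop over every
# 2x2 plaquette, wrapping each edge difference through atan2
oracle_winding <- function(theta) {
  ny <- nrow(theta); nx <- ncol(theta)
  out <- data.frame(ix = integer(0), iy = integer(0), chirality = integer(0))
  wrap <- function(d) atan2(sin(d), cos(d))
  for (iy in 1:(ny - 1)) for (ix in 1:(nx - 1)) {
    s <- wrap(theta[iy, ix + 1] - theta[iy, ix]) +
         wrap(theta[iy + 1, ix + 1] - theta[iy, ix + 1]) +
         wrap(theta[iy + 1, ix] - theta[iy + 1, ix + 1]) +
         wrap(theta[iy, ix] - theta[iy + 1, ix])
    w <- round(s / (2 * pi))
    if (w != 0)
      out <- rbind(out, data.frame(ix = ix, iy = iy, chirality = w))
  }
  out
}

# random multi-spiral field with k singularities away from edges and from
# each other; returns field plus ground truth
random_spiral_field <- function(nx = 40, ny = 40, k = 2, margin = 8,
                                min_sep = 8) {
  repeat {
    xs <- runif(k, margin + 1, nx - margin)
    ys <- runif(k, margin + 1, ny - margin)
    if (k < 2) break
    d <- as.matrix(dist(cbind(xs, ys)))
    if (min(d[upper.tri(d)]) > min_sep) break
  }
  ch <- sample(c(-1L, 1L), k, replace = TRUE)
  list(theta = synth_phase_field(nx, ny, xs, ys, ch),
       xs = xs, ys = ys, ch = ch)
}

# minimal tissue_recording stand-in for probe-based measurements
fake_cable_recording <- function(times, vm_by_probe, probes, grid) {
  structure(list(frames = NULL, frame_time = times,
                 probe_vm = vm_by_probe, probe_time = times,
                 probes = probes, grid = grid),
            class = "tissue_recording")
}

fast_curves <- function() dose_response_curves()

# short paced run used by several tests (memoised per session)
.pace_cache <- new.env(parent = emptyenv())
cached_pace <- function(iso, n_beats = 120, pcl = 1000) {
  key <- sprintf("i%s_n%d_p%d", iso, n_beats, pcl)
  if (is.null(.pace_cache[[key]]))
    .pace_cache[[key]] <- pace_to_steady_state(iso, pcl = pcl,
                                               n_beats = n_beats)
  .pace_cache[[key]]
}
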