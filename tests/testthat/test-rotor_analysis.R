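test_that("a single archimedean spiral yields one PS at the core", {
  th <- synth_phase_field(40, 40, 20.5, 20.5, +1, twist = 0.2)
  ps <- detect_phase_singularities(th, dx_cm = 0.04)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$chirality, 1L)
  expect_lt(abs(ps$ix - 20), 1.5)
  expect_lt(abs(ps$iy - 20), 1.5)
})

test_that("a planar wave has no phase singularities", {
  gx <- matrix(rep(1:40, each = 40), nrow = 40)
  th <- atan2(sin(0.3 * gx), cos(0.3 * gx))
  ps <- detect_phase_singularities(th, dx_cm = 0.04)
  expect_equal(nrow(ps), 0)
})

test_that("a figure-of-eight field has two PS of opposite chirality", {
  th <- synth_phase_field(50, 50, c(17.5, 32.5), c(25.5, 25.5), c(1, -1))
  ps <- detect_phase_singularities(th, dx_cm = 0.04)
  expect_equal(nrow(ps), 2)
  expect_equal(sort(ps$chirality), c(-1L, 1L))
  expect_lt(min(abs(ps$ix - 17.5)), 1.5)
  expect_lt(min(abs(ps$ix - 32.5)), 1.5)
})

test_that("detector matches the brute-force winding oracle on random fields", {
  set.seed(42)
  n_fields <- 100
  for (i in seq_len(n_fields)) {
    fld <- random_spiral_field(nx = 30, ny = 30,
                               k = sample(1:3, 1), margin = 7)
    ps <- detect_phase_singularities(fld$theta, dx_cm = 0.04,
                                     edge_margin = 5)
    orc <- oracle_winding(fld$theta)
    # restrict oracle to the same interior margin
    orc <- orc[orc$ix > 5 & orc$iy > 5 & orc$ix <= 25 & orc$iy <= 25, ]
    expect_equal(nrow(ps), nrow(orc), info = sprintf("field %d", i))
    if (nrow(orc)) {
      for (j in seq_len(nrow(orc))) {
        d <- abs(ps$ix - orc$ix[j]) + abs(ps$iy - orc$iy[j])
        expect_lte(min(d), 1)
        expect_equal(ps$chirality[which.min(d)], orc$chirality[j])
      }
    }
  }
})

test_that("topological charge is conserved on synthetic pair fields", {
  set.seed(7)
  for (i in 1:20) {
    fld <- random_spiral_field(nx = 30, ny = 30, k = 2, margin = 7)
    orc <- oracle_winding(fld$theta)
    expect_equal(sum(orc$chirality), sum(fld$ch))
  }
})

test_that("rotating a phase field rotates the detections with it", {
  th <- synth_phase_field(41, 41, 15.5, 23.5, +1, twist = 0.15)
  ps <- detect_phase_singularities(th, dx_cm = 0.04)
  th90 <- t(th)[, ncol(th):1]  # th90[i, j] = th[n + 1 - j, i]
  ps90 <- detect_phase_singularities(th90, dx_cm = 0.04)
  expect_equal(nrow(ps), 1); expect_equal(nrow(ps90), 1)
  # the core maps to (row = ix, col = n + 1 - iy), within a node
  expect_lt(abs(ps90$iy - ps$ix), 2)
  expect_lt(abs(ps90$ix - (41 - ps$iy)), 2)
})

test_that("tracking links stationary and slowly moving singularities", {
  times <- seq(0, 198, by = 2)
  mk_frames <- function(xs_t, ys_t, ch = 1) {
    lapply(seq_along(times), function(i)
      data.frame(x_mm = xs_t[i], y_mm = ys_t[i], ix = NA, iy = NA,
                 chirality = ch))
  }
  trs <- track_singularities(mk_frames(rep(10, 100), rep(10, 100)),
                             times = times)
  expect_equal(length(trs), 1)
  expect_equal(attr(trs[[1]], "lifetime"), 198)
  # 0.2 mm per frame drift stays under the 4 mm link radius
  trs2 <- track_singularities(mk_frames(10 + 0.2 * seq_len(100),
                                        rep(10, 100)), times = times)
  expect_equal(length(trs2), 1)
})

test_that("chirality matching keeps crossing singularities separate", {
  times <- seq(0, 98, by = 2)
  n <- length(times)
  det <- lapply(seq_len(n), function(i) {
    data.frame(x_mm = c(5 + 0.4 * i, 25 - 0.4 * i), y_mm = c(10, 10),
               ix = NA, iy = NA, chirality = c(1L, -1L))
  })
  trs <- track_singularities(det, times = times)
  expect_equal(length(trs), 2)
  ch <- sort(vapply(trs, function(tr) tr$chirality[1], integer(1)))
  expect_equal(ch, c(-1L, 1L))
  expect_true(all(vapply(trs, function(tr) nrow(tr) == n, logical(1))))
})

test_that("angular speed counts probe phase revolutions over the window", {
  # synthetic recording: every node oscillates at 4 Hz; a fixed PS track
  g <- build_sheet(40, 40)
  times <- seq(0, 2000, by = 2)
  vm <- matrix(rep(-60 + 40 * cos(2 * pi * 4 * times / 1000),
                   times = 1600), nrow = length(times))
  rec <- structure(list(frames = vm, frame_time = times, grid = g),
                   class = "tissue_recording")
  track <- data.frame(time = times, x_mm = 8, y_mm = 8, chirality = 1L)
  attr(track, "lifetime") <- 2000
  expect_equal(angular_speed(track, rec, window = 2000), 4,
               tolerance = 0.05)
})

test_that("localization area counts distinct visited elements", {
  mk_track <- function(x, y, times) {
    tr <- data.frame(time = times, x_mm = x, y_mm = y, chirality = 1L)
    attr(tr, "lifetime") <- max(times) - min(times)
    tr
  }
  times <- seq(0, 4000, by = 2)
  still <- mk_track(rep(10.05, length(times)), rep(10.05, length(times)),
                    times)
  expect_equal(as.numeric(localization_area(still)), 0.16)
  # straight line across n distinct 0.4 mm elements
  n <- 12
  line <- mk_track(0.2 + 0.4 * rep(0:(n - 1), length.out = length(times)),
                   rep(10.05, length(times)), times)
  expect_equal(as.numeric(localization_area(line)), n * 0.16)
  short <- mk_track(rep(10, 50), rep(10, 50), seq(0, 98, by = 2))
  expect_warning(a <- localization_area(short), "shorter")
  expect_true(attr(a, "short_track"))
})

test_that("wavelet counting filters transient tracks", {
  times <- seq(0, 1000, by = 2)
  mk <- function(t0, t1) {
    sel <- times >= t0 & times <= t1
    tr <- data.frame(time = times[sel], x_mm = 1, y_mm = 1, chirality = 1L)
    attr(tr, "lifetime") <- t1 - t0
    tr
  }
  tracks <- structure(list(mk(0, 1000), mk(0, 1000), mk(500, 520)),
                      class = "ps_tracks")
  expect_equal(count_wavelets(tracks, times = times, min_lifetime = 100), 2)
  single <- structure(list(mk(0, 1000)), class = "ps_tracks")
  expect_equal(count_wavelets(single, times = times), 1)
})
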