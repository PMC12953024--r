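test_that("sheet construction arithmetic matches the physical dimensions", {
  g <- sheet_from_cm(6, 6)
  expect_equal(c(g$nx, g$ny), c(150L, 150L))
  expect_equal(g$nx * g$dx_cm * g$ny * g$dx_cm, 36)
  g2 <- sheet_from_cm(9, 6)
  expect_equal(c(g2$nx, g2$ny), c(225L, 150L))
  cab <- sheet_from_cm(1)
  expect_equal(c(cab$nx, cab$ny), c(25L, 1L))
  expect_equal(g$sigma_l / g$sigma_t, 0.1608 / 0.0448, tolerance = 1e-12)
  expect_error(build_sheet(0, 5))
})

test_that("density maps flag the requested element count reproducibly", {
  g <- build_sheet(150, 150)
  m0 <- assign_bars_density(g, 0, seed = 1)
  expect_equal(sum(m0$flag), 0)
  m <- assign_bars_density(g, 0.05, seed = 1)
  expect_equal(sum(m$flag), 1125)
  m2 <- assign_bars_density(g, 0.05, seed = 1)
  expect_identical(m$flag, m2$flag)
  m3 <- assign_bars_density(g, 0.05, seed = 2)
  expect_false(identical(m$flag, m3$flag))
  expect_equal(sum(m3$flag), 1125)
})

test_that("gradient maps build three regions around the 20% base", {
  g <- build_sheet(225, 150)
  m <- assign_bars_gradient(g, 0.20, seed = 3)
  expect_equal(m$region_density, c(0, 0.2, 0.4))
  per_region <- function(map, r) {
    cols <- ((r - 1) * 75 + 1):(r * 75)
    idx <- as.vector(outer(cols, (0:149) * 225, `+`))
    sum(map$flag[idx])
  }
  expect_equal(per_region(m, 1), 0)
  expect_equal(per_region(m, 2), round(0.2 * 75 * 150))
  expect_equal(per_region(m, 3), round(0.4 * 75 * 150))
  m5 <- assign_bars_gradient(g, 0.05, seed = 3)
  expect_equal(per_region(m5, 1), round(0.15 * 75 * 150))
  expect_equal(per_region(m5, 3), round(0.25 * 75 * 150))
  md0 <- assign_bars_gradient(g, 0, seed = 3)
  expect_equal(sum(md0$flag), 3 * round(0.2 * 75 * 150))
  expect_warning(assign_bars_gradient(g, 0.25, seed = 3), "clamped")
})

test_that("volumetric stimulus conversion divides by Am Cm", {
  g <- build_sheet(10, 10)
  expect_equal(stim_amp_from_uAcm3(250, g), 250 / 1400)
})

test_that("uniform membrane potential diffuses to exactly zero flux", {
  g <- build_sheet(12, 12)
  r <- monodomain_simulate(g, list(), duration = 5, frame_dt = 1)
  v <- r$frames
  expect_equal(max(apply(v, 1, function(row) diff(range(row)))), 0)
})

test_that("a left-edge stimulus launches a planar y-invariant wavefront", {
  g <- build_sheet(30, 12)
  s <- tissue_stimulus(region = as.vector(outer(1:2, (0:11) * 30, `+`)),
                       amplitude = 40, onset = 0, dur = 2)
  r <- monodomain_simulate(g, s, duration = 30, frame_dt = 5)
  fr <- matrix(r$frames[nrow(r$frames), ], nrow = 12, byrow = TRUE)
  # all rows identical: isochrones parallel to the stimulated edge
  expect_lt(max(apply(fr, 2, function(col) diff(range(col)))), 1e-9)
  # and the wave actually propagated
  expect_gt(max(fr), -40)
})

test_that("tissue runs at ISO 0 are identical with the machinery disabled", {
  g <- build_sheet(20, 1)
  s <- tissue_stimulus(region = 1:2, amplitude = 30, onset = 0, dur = 5)
  r_on <- monodomain_simulate(g, s, duration = 40, iso = 0, bars = TRUE,
                              frame_dt = 2)
  r_off <- monodomain_simulate(g, s, duration = 40, iso = 0, bars = FALSE,
                               frame_dt = 2)
  expect_identical(r_on$frames, r_off$frames)
  expect_identical(r_on$final_states, r_off$final_states)
})

test_that("cable CV follows probe activation times exactly", {
  g <- build_sheet(25, 1)
  probes <- cable_probe_nodes(g)
  # synthetic 1 ms/mm wave: 0.48 cm between probes in 4.8 ms -> 100 cm/s
  times <- seq(0, 40, by = 0.1)
  mk <- function(t0) -85 + 100 / (1 + exp(-(times - t0) / 0.5))
  vm <- cbind(mk(10), mk(14.8))
  rec <- fake_cable_recording(times, vm, probes, g)
  expect_equal(measure_cable_cv(rec), 100, tolerance = 0.03)
  # conduction block: distal probe silent
  vm2 <- cbind(mk(10), rep(-85, length(times)))
  rec2 <- fake_cable_recording(times, vm2, probes, g)
  expect_warning(cv <- measure_cable_cv(rec2), "block")
  expect_true(is.na(cv))
})

test_that("a propagating cable beat yields a physiological CV", {
  g <- build_sheet(25, 1, sigma_l = 0.15, sigma_t = 0.07)
  cs <- cached_pace(0, n_beats = 150)$final_state
  s <- tissue_stimulus(region = 1:2, amplitude = 35, onset = 0, dur = 5)
  r <- monodomain_simulate(g, s, duration = 60, init = cs,
                           probes = cable_probe_nodes(g), frame_dt = 20)
  cv <- measure_cable_cv(r)
  expect_gt(cv, 30); expect_lt(cv, 90)
})

test_that("per-element conductance scaling maps modulate repolarization", {
  g <- build_sheet(20, 1)
  cs <- cached_pace(0, n_beats = 150)$final_state
  s <- tissue_stimulus(region = 1:2, amplitude = 35, onset = 0, dur = 5)
  base <- monodomain_simulate(g, s, duration = 400, init = cs,
                              probes = 10L, frame_dt = 100)
  gkr_half <- monodomain_simulate(g, s, duration = 400, init = cs,
                                  probes = 10L, frame_dt = 100,
                                  scale_map = list(gkr = rep(0.5, 20)))
  # halved GKr prolongs repolarization at the probe
  v_base <- base$probe_vm[, 1]; v_mod <- gkr_half$probe_vm[, 1]
  t_rep <- function(v, tm) tm[which(v < -70 & tm > 50)[1]]
  expect_gt(t_rep(v_mod, gkr_half$probe_time),
            t_rep(v_base, base$probe_time))
})
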