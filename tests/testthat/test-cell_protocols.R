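test_that("AP features of a synthetic square pulse are exact", {
  tm <- seq(0, 400, by = 0.5)
  vm <- ifelse(tm >= 10 & tm < 210, 15, -85)  # 100 mV square, 200 ms
  f <- ap_features_from_series(tm, vm)
  expect_equal(f$apd90, 200, tolerance = 0.5)
  expect_equal(f$peak_vm, 15)
  expect_equal(f$resting_vm, -85)
  expect_true(f$captured)
})

test_that("a beat without an action potential is flagged", {
  tm <- seq(0, 400, by = 0.5)
  vm <- -85 + 5 * exp(-(tm - 10)^2 / 100)   # subthreshold bump
  f <- ap_features_from_series(tm, vm)
  expect_false(f$captured)
  expect_true(is.na(f$apd90))
})

test_that("steady 1 Hz pacing reproduces the baseline action potential", {
  p <- cached_pace(0, n_beats = 150)
  f <- measure_features(p)
  expect_gt(f$apd90, 280); expect_lt(f$apd90, 320)
  expect_gt(f$peak_vm, 35)
  expect_lt(f$resting_vm, -80)
  expect_gt(f$max_upstroke, 100)
  expect_gt(f$cat_amplitude, 0)
  expect_true(all(p$beats$captured == 1L))
})

test_that("saturating ISO shortens the AP and enlarges the Ca transient", {
  p0 <- cached_pace(0, n_beats = 150)
  p1 <- cached_pace(1, n_beats = 150)
  f0 <- measure_features(p0); f1 <- measure_features(p1)
  expect_lt(f1$apd90, f0$apd90)
  expect_gt(f1$cat_amplitude, f0$cat_amplitude)
  expect_lt(f1$cat_duration, f0$cat_duration)
  expect_gt(f1$peak_vm, f0$peak_vm - 3)
})

test_that("voltage clamp is clamped and self-normalization is unity", {
  prot <- clamp_protocol("ICaL")
  prot$step_vms <- c(-20, -10, 0)
  prot$step_ms <- 100
  rest <- cell_state()
  iv <- voltage_clamp_iv("ICaL", iso = 0, protocol = prot, state0 = rest)
  expect_equal(nrow(iv), 3)
  expect_true(all(iv$peak < 0))
  ivn <- voltage_clamp_iv("ICaL", iso = 0, protocol = prot, state0 = rest,
                          normalize = TRUE, n_precondition_beats = 1)
  expect_equal(ivn$ratio, rep(1, 3))
})

test_that("baseline ICaL I-V peaks near -10 to 0 mV", {
  iv <- voltage_clamp_iv("ICaL", iso = 0, state0 = cell_state())
  vpk <- iv$step_vm[which.min(iv$peak)]
  expect_true(vpk >= -15 && vpk <= 5)
})

test_that("unknown clamp channels are rejected", {
  expect_error(voltage_clamp_iv("IKr"), "arg")
})

test_that("Na availability falls with depolarized conditioning", {
  av <- na_availability(vms = c(-120, -100, -80), iso = 0,
                        state0 = cell_state())
  expect_true(all(diff(av$availability) < 0))
  expect_gt(av$availability[1], 0.9)
})

test_that("APD restitution shortens APD at short cycle lengths", {
  rc <- apd_restitution(0, pcl_start = 1000, pcl_step = -300,
                        pcl_min = 250, n_beats = 30)
  ok <- rc$captured
  expect_gte(sum(ok), 2)
  apd <- rc$apd90[ok]; pcl <- rc$pcl[ok]
  expect_true(all(diff(apd[order(pcl)]) >= 0))  # APD nondecreasing in PCL
  expect_true(all(rc$di[ok][-1] <= rc$pcl[ok][-1], na.rm = TRUE))
})
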