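test_that("band-pass keeps in-band tones and removes DC and 50 Hz", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  x5 <- cos(2 * pi * 5 * t)
  y5 <- bandpass(x5, fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_gt(sd(y5[mid]) / sd(x5[mid]), 0.99)
  ydc <- bandpass(x5 + 30, fs)
  expect_lt(abs(mean(ydc)), 1e-6 * 30)
  x50 <- cos(2 * pi * 50 * t)
  y50 <- bandpass(x50, fs)
  atten_db <- 20 * log10(sd(x50[mid]) / sd(y50[mid]))
  expect_gt(atten_db, 20)
  expect_error(bandpass(x5[1:5], fs), "transient")
})

test_that("Hilbert phase of a cosine is a linear ramp of slope 2 pi f", {
  fs <- 500; f <- 5
  t <- seq(0, 4, by = 1 / fs)[-1]
  th <- instantaneous_phase(cos(2 * pi * f * t))
  un <- unwrap_phase(th)
  trim <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  fit <- lm(un[trim] ~ t[trim])
  expect_equal(unname(coef(fit)[2]), 2 * pi * f, tolerance = 1e-4)
  resid <- un[trim] - (coef(fit)[1] + coef(fit)[2] * t[trim])
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("a sine lags the cosine phase by pi/2 everywhere", {
  fs <- 500; f <- 5
  t <- seq(0, 2, by = 1 / fs)[-1]
  thc <- instantaneous_phase(cos(2 * pi * f * t))
  ths <- instantaneous_phase(sin(2 * pi * f * t))
  trim <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  d <- atan2(sin(thc - ths), cos(thc - ths))
  expect_equal(mean(d[trim]), pi / 2, tolerance = 1e-3)
  expect_lt(max(abs(d[trim] - pi / 2)), 1e-2)
})

test_that("a paced AP train advances the Hilbert phase 2 pi per beat", {
  tr <- integrate_cell(duration = 3000, stim_onsets = c(0, 600, 1200, 1800,
                                                        2400),
                       stim_amp = 60, stim_dur = 1, record_dt = 2)
  x <- bandpass(tr$Vm, fs = 500)
  un <- unwrap_phase(instantaneous_phase(x))
  # 4 full cycles between the first and last beat, within half a cycle
  adv <- abs(un[length(un)] - un[1]) / (2 * pi)
  expect_gt(adv, 3.5); expect_lt(adv, 5.5)
})

test_that("all-zero signals yield undefined phase", {
  expect_true(all(is.na(instantaneous_phase(rep(0, 100)))))
})
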