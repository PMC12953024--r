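test_that("phosphorylation fractions follow the Hill dose-response", {
  crv <- dose_response_curves()
  a0 <- phosphorylation_profile(0, crv)
  expect_equal(unname(unclass(a0)), rep(0, 9))

  # saturating agonist: every alpha within 1% of its plateau
  a1 <- phosphorylation_profile(1, crv)
  expect_true(all(a1 >= 0.99 * crv$alpha_max))
  expect_true(all(a1 <= crv$alpha_max))

  # monotone in ISO for every target
  isos <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 10)
  mat <- sapply(isos, phosphorylation_profile, curves = crv)
  expect_true(all(apply(mat, 1, function(r) all(diff(r) > 0))))

  # closed form check at one interior dose against direct arithmetic
  a <- phosphorylation_profile(0.01, crv)
  expect_equal(unname(a["INa"]),
               crv$alpha_max[1] * 0.01^2 / (crv$ec50[1]^2 + 0.01^2))
})

test_that("invalid dose-response inputs are rejected", {
  expect_error(phosphorylation_profile(-0.1), "non-negative")
  expect_error(phosphorylation_profile(c(1, 2)), "single")
  expect_error(dose_response_curves(ec50 = -1))
  expect_error(dose_response_curves(alpha_max = 1.2))
})

test_that("modifier defaults validate and reject unknown names", {
  m <- bars_modifiers()
  expect_equal(m$gNa_scale, 1.7)
  expect_equal(m$gCaL_scale, 3.0)
  expect_equal(m$gKs_scale, 2.5)
  expect_equal(m$kmNa_scale, 0.7)
  expect_equal(m$kBufc_scale, 1.7)
  m2 <- bars_modifiers(gCaL_scale = 2)
  expect_equal(m2$gCaL_scale, 2)
  expect_error(bars_modifiers(nope = 1), "unknown")
  expect_error(bars_modifiers(gNa_scale = -1), "> 0")
})
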