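state_mid_ap <- function() {
  # a state partway through an action potential (gives nonzero currents)
  tr <- integrate_cell(duration = 120, stim_onsets = 5, record_dt = 1)
  attr(tr, "final_state")
}

test_that("net currents mix linearly between populations", {
  y <- state_mid_ap()
  tg <- bars_targets()
  for (k in seq_along(tg)) {
    for (a in c(0, 0.25, 0.5, 1)) {
      al <- rep(0, 9); al[k] <- a
      cs <- membrane_currents(y, al)
      if (tg[k] == "Kbufc") {
        expect_equal(unname(cs["Kbufc_eff"]), 0.001 * (1 + a * 0.7))
        next
      }
      np <- cs[paste0(tg[k], "_NP")]
      pp <- cs[paste0(tg[k], "_P")]
      expect_equal(unname(cs[tg[k]]), unname(np + a * (pp - np)))
    }
  }
  # alpha = 0.5 gives the arithmetic mean of the two populations
  al <- rep(0, 9); al[2] <- 0.5
  cs <- membrane_currents(y, al)
  expect_equal(unname(cs["ICaL"]),
               unname((cs["ICaL_NP"] + cs["ICaL_P"]) / 2))
})

test_that("phosphorylated conductance scalings appear in the P currents", {
  y <- state_mid_ap()
  cs <- membrane_currents(y, rep(1, 9))
  # INa_P uses 1.7 x GNa with the same m gate; gate states identical at
  # this alpha-naive state only for j; check via an explicit h_P = h state
  y2 <- y; nm <- cpp_state_names()
  y2[nm %in% c("h_P", "j_P")] <- y2[nm %in% c("h", "j")]
  cs2 <- membrane_currents(y2, rep(1, 9))
  expect_equal(unname(cs2["INa_P"] / cs2["INa_NP"]), 1.7, tolerance = 1e-12)
  # IKs_P conductance factor with matched gates
  y3 <- y; y3[nm == "xs_P"] <- y3[nm == "xs"]
  cs3 <- membrane_currents(y3, rep(1, 9))
  expect_equal(unname(cs3["IKs_P"] / cs3["IKs_NP"]), 2.5, tolerance = 1e-12)
  # algebraically mixed targets need no gate alignment
  expect_equal(unname(cs["Ixfer_P"] / cs["Ixfer_NP"]), 2.1, tolerance = 1e-12)
  expect_gt(unname(cs["IpK_P"] / cs["IpK_NP"]), 0)
  # SR leak is never modified: absent from the P/NP pairs
  expect_false("Ileak_P" %in% names(cs))
})

test_that("zero phosphorylation reproduces the baseline model exactly", {
  y <- state_mid_ap()
  a0 <- rep(0, 9)
  cs_on <- membrane_currents(y, a0, bars = TRUE)
  cs_off <- membrane_currents(y, a0, bars = FALSE)
  expect_identical(cs_on, cs_off)
  # and the modifiers are irrelevant at ISO = 0
  cs_mod <- membrane_currents(y, a0, mods = bars_modifiers(gCaL_scale = 9,
                                                           gNa_scale = 5))
  expect_identical(cs_on[c("INa", "ICaL", "IKs", "Itot")],
                   cs_mod[c("INa", "ICaL", "IKs", "Itot")])
})

test_that("the stimulus enters dVm/dt linearly with unit capacitance", {
  y <- cell_state()
  d0 <- state_derivative(y, istim = 0)
  d1 <- state_derivative(y, istim = 60)
  expect_equal(unname(d1["Vm"] - d0["Vm"]), 60)
  gates <- setdiff(cpp_state_names(), c("Vm", "Ki"))
  expect_equal(d0[gates], d1[gates])
})

test_that("the relaxed resting state is a fixed point of the dynamics", {
  tr <- integrate_cell(duration = 2000, record_dt = 500)
  y <- attr(tr, "final_state")
  d <- state_derivative(y)
  expect_lt(abs(d["Vm"]), 1e-3)
  # stepping ISO to saturation perturbs the Ca-handling derivatives
  d_iso <- state_derivative(y, phosphorylation_profile(1))
  expect_gt(abs(d_iso["Cai"] - d["Cai"]) + abs(d_iso["CaSR"] - d["CaSR"]) +
            abs(d_iso["Vm"] - d["Vm"]), 0)
})

test_that("unstimulated integration from rest stays at rest", {
  tr <- integrate_cell(duration = 1000, record_dt = 10)
  expect_lt(max(tr$Vm) - min(tr$Vm), 0.5)
})

test_that("integrator keeps gates bounded and concentrations positive", {
  tr <- integrate_cell(iso = 1, duration = 600,
                       stim_onsets = c(10, 310), record_dt = 1)
  nm <- cpp_state_names()
  gates <- nm[7:26][!nm[7:26] %in% c("Nai", "Ki", "Cai", "CaSS", "CaSR")]
  for (g in intersect(gates, names(tr)))
    expect_true(all(tr[[g]] >= 0 & tr[[g]] <= 1), info = g)
  for (cc in c("Nai", "Ki", "Cai", "CaSS", "CaSR"))
    expect_true(all(tr[[cc]] > 0), info = cc)
})

test_that("halving the step changes a paced action potential very little", {
  p1 <- pace_to_steady_state(0, n_beats = 3, dt = 0.02)
  p2 <- pace_to_steady_state(0, n_beats = 3, dt = 0.01)
  a1 <- tail(p1$beats$apd90, 1)
  a2 <- tail(p2$beats$apd90, 1)
  expect_lt(abs(a1 - a2), 1)
})

test_that("tabulated stepping agrees with direct evaluation", {
  # one paced beat recorded through the table-driven stepper, then the
  # direct right-hand side re-evaluated at recorded states: the recorded
  # currents come from rhs_direct already, so instead compare a short
  # two-step trajectory against an Euler/RL step built from cpp_rhs
  y <- cell_state()
  tr <- integrate_cell(duration = 1, dt = 0.02, record_dt = 0.02,
                       stim_onsets = 0, stim_amp = 60, stim_dur = 1)
  # concentrations follow forward Euler of the direct derivative
  d <- state_derivative(as.numeric(tr[1, 2:27]), istim = 60)
  expect_equal(tr$Cai[2], tr$Cai[1] + 0.02 * unname(d["Cai"]),
               tolerance = 1e-6)
  expect_equal(tr$Vm[2], tr$Vm[1] + 0.02 * unname(d["Vm"]),
               tolerance = 1e-4)
})

test_that("numerical blow-up is reported with diagnostics", {
  expect_error(integrate_cell(duration = 50, stim_onsets = 0,
                              stim_amp = 1e5, stim_dur = 50),
               "blow-up")
})
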