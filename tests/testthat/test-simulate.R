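test_that("a zero-dose protocol stays at the pre-stimulation steady state", {
  sim <- her_simulate(truth_params, her_profile("D20"),
                      times = c(0, 30, 120))
  drift <- max(abs(sweep(sim$states, 2, sim$states[1, ]))) /
    max(sim$states[1, ])
  expect_lt(drift, 1e-6)
})

test_that("doubling kon and koff preserves binding equilibria without trafficking", {
  # same Kd -> same t -> infinity occupancy for the reversible binding
  # subsystem (trafficking and dimerization off; the irreversible
  # collapse pathway scales with koff and is excluded on purpose)
  mk <- function(fac) {
    her_parameters(binding = list(
      kon1s = 0.097 * fac, koff1s = 0.24 * fac,
      kon1e = 0.097, koff1e = 2.0,
      kon3s = 0.060 * fac, koff3s = 0.12 * fac,
      kon3e = 0.097, koff3e = 2.0),
      kc = c(s = 0, e = 0),
      trafficking = list(her1 = c(kt = 0, ke = 0, kx = 0.15, f = 0.5),
                         her23 = c(kt = 0, ke = 0, kx = 0.15, f = 0.85)))
  }
  run <- function(p) {
    state0 <- setNames(numeric(51), her_state_names())
    state0["R1_s"] <- 2e5; state0["R3_s"] <- 4e4
    state0["E_s"] <- 12 / 6.4; state0["H_s"] <- 40 / 7.5
    sol <- herdimer:::.integrate_states(state0, p, times = c(0, 5000))
    sol[2, -1]
  }
  s1 <- run(mk(1)); s2 <- run(mk(2))
  expect_equal(s1, s2, tolerance = 1e-7)
  # occupancy matches the closed-form Kd prediction
  kd <- 0.24 / 0.097
  e <- 12 / 6.4
  expect_equal(unname(s1[which(her_state_names() == "R1E_s")]) /
                 (2e5 - s1[which(her_state_names() == "R1E_s")]),
               e / kd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("observables implement the pf-weighted linear readout", {
  pf <- her_free_values(truth_params)
  pf_named <- pf[grepl("^pf", names(pf))]
  pf_named[] <- 0
  pf_named["pf12es"] <- 0.02
  pf_named["pf21es"] <- 0.05
  p <- her_set_free(truth_params, pf_named)
  state <- setNames(numeric(51), her_state_names())
  state["R12E_s"] <- 10
  obs <- her_observables(state, p)
  expect_equal(unname(obs[1, "pR1t"]), 0.2)
  expect_equal(unname(obs[1, "pR2t"]), 0.5)
  expect_equal(unname(obs[1, "pR3t"]), 0)
  expect_equal(unname(obs[1, "pR1i"]), 0)
  # all pf zero -> all phospho observables zero
  p0 <- her_set_free(truth_params, setNames(rep(0, sum(grepl("^pf", names(pf)))),
                                            names(pf_named)))
  obs0 <- her_observables(random_state(5), p0)
  expect_equal(unname(obs0[1, 1:6]), rep(0, 6))
})

test_that("HER3 homodimers never contribute to pR3", {
  state <- setNames(numeric(51), her_state_names())
  state["R33H_s"] <- 1000
  state["R33HH_s"] <- 1000
  state["R33H_e"] <- 1000
  obs <- her_observables(state, truth_params)
  expect_equal(unname(obs[1, "pR3t"]), 0)
  expect_equal(unname(obs[1, "mR3t"]), 2 * (1000 + 1000 + 1000))
})

test_that("late-endosome species count toward mass but not phospho", {
  state <- setNames(numeric(51), her_state_names())
  state["R11EE_l"] <- 500
  obs <- her_observables(state, truth_params)
  expect_equal(unname(obs[1, "pR1t"]), 0)
  expect_equal(unname(obs[1, "mR1t"]), 1000)
})

test_that("internal phospho is bounded by total phospho along trajectories", {
  sim <- her_simulate(truth_params, her_profile("D20"), egf_ng_ml = 12,
                      hrg_ng_ml = 40, times = seq(0, 120, by = 10))
  for (i in 1:3) {
    expect_true(all(sim$observables[, paste0("pR", i, "i")] <=
                      sim$observables[, paste0("pR", i, "t")] + 1e-9))
    expect_true(all(sim$observables[, paste0("mR", i, "t")] >= 0))
  }
})

test_that("turning off internalization removes the internal signal", {
  p <- her_parameters(trafficking = list(
    her1 = c(kt = 0, ke = 0, kx = 0.15, f = 0.5),
    her23 = c(kt = 0, ke = 0, kx = 0.15, f = 0.85)))
  sim <- her_simulate(p, her_profile("D20"), egf_ng_ml = 12, hrg_ng_ml = 40,
                      times = c(0, 30, 60))
  expect_equal(max(sim$observables[, c("pR1i", "pR2i", "pR3i")]), 0)
})

test_that("HER2 blocking scales the reactive pool and kills pR2t at full block", {
  prof <- her_profile("D20")
  blk <- her_apply_block(prof, 0.95)
  expect_equal(blk$available$her2, 0.05 * prof$her2)
  expect_equal(blk$sequestered_her2, 0.95 * prof$her2)
  expect_error(her_apply_block(prof, 1.2), "\\[0, 1\\]")

  sim_full <- her_simulate(truth_params, prof, egf_ng_ml = 12,
                           hrg_ng_ml = 40, times = c(0, 10, 30),
                           block_fraction = 1)
  expect_equal(max(sim_full$observables[, "pR2t"]), 0)
  # sequestered HER2 still counts in the mass observable
  expect_gt(min(sim_full$observables[, "mR2t"]), 0.9 * prof$her2)

  sim0 <- her_simulate(truth_params, prof, egf_ng_ml = 12, hrg_ng_ml = 40,
                       times = c(0, 10, 30), block_fraction = 0)
  sim_ref <- her_simulate(truth_params, prof, egf_ng_ml = 12, hrg_ng_ml = 40,
                          times = c(0, 10, 30))
  expect_equal(sim0$observables, sim_ref$observables, tolerance = 1e-10)
})

test_that("pR2t decreases monotonically with the blocked fraction", {
  fr <- c(0, 0.5, 0.95, 1)
  p2 <- sapply(fr, function(f)
    her_simulate(truth_params, her_profile("D20"), egf_ng_ml = 12,
                 hrg_ng_ml = 40, times = c(0, 10, 30),
                 block_fraction = f)$observables[, "pR2t"])
  for (j in seq_len(length(fr) - 1))
    expect_true(all(p2[, j + 1] <= p2[, j] + 1e-9))
})

test_that("raising a pf raises the matching observable", {
  sim_lo <- her_simulate(truth_params, her_profile("D20"), egf_ng_ml = 12,
                         times = c(0, 30))
  p_hi <- her_set_free(truth_params, c(pf12es = truth_params$pf[["pf12es"]] * 2))
  sim_hi <- her_simulate(p_hi, her_profile("D20"), egf_ng_ml = 12,
                         times = c(0, 30))
  expect_gt(sim_hi$observables[2, "pR1t"], sim_lo$observables[2, "pR1t"])
})
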