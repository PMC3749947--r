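make_sim_from_state <- function(state, params = truth_params) {
  structure(list(times = 0, states = matrix(state, nrow = 1,
                                            dimnames = list(NULL, names(state))),
                 observables = her_observables(state, params),
                 profile = her_profile("hand", her1 = 1, her2 = 1, her3 = 1),
                 egf_ng_ml = 0, hrg_ng_ml = 0, block_fraction = 0,
                 params = params), class = "her_sim")
}

test_that("a single active dimer owns 100% of its receptor signal", {
  state <- setNames(numeric(51), her_state_names())
  state["R11EE_s"] <- 50
  dec <- her_decompose(make_sim_from_state(state), time = 0)
  r1 <- dec[dec$receptor == "pR1", ]
  expect_equal(r1$fraction[r1$dimer == "R11EE"], 1)
  expect_true(all(is.na(dec$fraction[dec$receptor == "pR3"])))
})

test_that("equal pf x abundance splits 50/50", {
  pf <- c(pf11ees = 0.1, pf12es = 0.2)
  p <- her_set_free(truth_params, pf)
  state <- setNames(numeric(51), her_state_names())
  state["R11EE_s"] <- 20   # 0.1 * 20 = 2
  state["R12E_s"] <- 10    # 0.2 * 10 = 2
  dec <- her_decompose(make_sim_from_state(state, p), time = 0)
  r1 <- dec[dec$receptor == "pR1" & dec$fraction > 0, ]
  expect_equal(sort(r1$fraction), c(0.5, 0.5))
})

test_that("hand-built HER2 decomposition gives 71.4% / 28.6%", {
  # [R12E] = 5 with pf21 = 0.1 and [R23H] = 4 with pf23 = 0.05:
  # signals 0.5 and 0.2 -> fractions 5/7 and 2/7
  pf <- setNames(rep(0, 26), grep("^pf", her_free_names(), value = TRUE))
  pf["pf21es"] <- 0.1
  pf["pf23hs"] <- 0.05
  p <- her_set_free(truth_params, pf)
  state <- setNames(numeric(51), her_state_names())
  state["R12E_s"] <- 5
  state["R23H_s"] <- 4
  dec <- her_decompose(make_sim_from_state(state, p), time = 0)
  r2 <- dec[dec$receptor == "pR2", ]
  expect_equal(r2$fraction[r2$dimer == "R12E"], 5 / 7, tolerance = 1e-9)
  expect_equal(r2$fraction[r2$dimer == "R23H"], 2 / 7, tolerance = 1e-9)
})

test_that("fractions sum to one and pair rollup aggregates occupancies", {
  sim <- her_simulate(truth_params, her_profile("D20"), egf_ng_ml = 30,
                      hrg_ng_ml = 100, times = c(0, 60))
  dec <- her_decompose(sim, time = 60)
  for (r in unique(dec$receptor)) {
    fr <- dec$fraction[dec$receptor == r]
    if (!all(is.na(fr))) expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
  pair <- her_decompose(sim, time = 60, level = "pair")
  r1s <- dec[dec$receptor == "pR1", ]
  expect_equal(pair$signal[pair$receptor == "pR1" & pair$dimer == "R11"],
               sum(r1s$signal[r1s$dimer %in% c("R11E", "R11EE")]))
})

test_that("zeroing a pf removes its dimer and renormalizes the rest", {
  sim <- her_simulate(truth_params, her_profile("D20"), egf_ng_ml = 30,
                      hrg_ng_ml = 100, times = c(0, 60))
  dec <- her_decompose(sim, time = 60)
  p0 <- her_set_free(truth_params, c(pf12es = 0, pf12ei = 0))
  sim0 <- her_simulate(p0, her_profile("D20"), egf_ng_ml = 30,
                       hrg_ng_ml = 100, times = c(0, 60))
  dec0 <- her_decompose(sim0, time = 60)
  r1 <- dec[dec$receptor == "pR1", ]
  r10 <- dec0[dec0$receptor == "pR1", ]
  expect_equal(r10$signal[r10$dimer == "R12E"], 0)
  keep <- r1$dimer != "R12E"
  expect_equal(r10$fraction[keep] / r1$fraction[keep],
               rep(sum(r1$signal) / sum(r10$signal), sum(keep)),
               tolerance = 1e-6)
})

test_that("grid scan is consistent with a direct single simulation", {
  p <- truth_params
  g <- her_grid_scan(p, her1_range = c(2e5, 2e5), her2_range = c(6e5, 6e5),
                     n = 1, her3 = 4e4)
  sim <- her_simulate(p, her_profile("D20"), egf_ng_ml = 30,
                      hrg_ng_ml = 100, times = c(0, 60))
  expect_equal(g$pR1t, unname(sim$observables[2, "pR1t"]), tolerance = 1e-8)
  expect_equal(g$pR3t, unname(sim$observables[2, "pR3t"]), tolerance = 1e-8)
})

test_that("pR3t grows with HER2 expression at fixed HER1", {
  her2_levels <- c(1e3, 1e4, 1e5, 1e6)
  p3 <- vapply(her2_levels, function(h2) {
    sim <- her_simulate(truth_params,
                        her_profile("x", her1 = 2e5, her2 = h2, her3 = 4e4),
                        egf_ng_ml = 30, hrg_ng_ml = 100, times = c(0, 60))
    sim$observables[2, "pR3t"]
  }, numeric(1))
  expect_true(all(diff(p3) > 0))
})

test_that("with HER1 >> HER2 the R13 dimers outweigh R23 in pR3", {
  sim <- her_simulate(truth_params,
                      her_profile("x", her1 = 1e6, her2 = 1e3, her3 = 4e4),
                      egf_ng_ml = 30, hrg_ng_ml = 100, times = c(0, 60))
  pair <- her_decompose(sim, time = 60, level = "pair")
  r3 <- pair[pair$receptor == "pR3", ]
  expect_gt(r3$signal[r3$dimer == "R13"], r3$signal[r3$dimer == "R23"])
})

test_that("panel prediction matches single simulations and handles edge cases", {
  empty <- her_panel_predict(truth_params, her_panel_fixture()[0, ])
  expect_equal(nrow(empty), 0L)
  one <- her_panel_fixture()[1, ]
  pp <- her_panel_predict(truth_params, one)
  sim <- her_simulate(truth_params,
                      her_profile(one$name, her1 = one$her1,
                                  her2 = one$her2, her3 = one$her3),
                      egf_ng_ml = 30, hrg_ng_ml = 100, times = c(0, 60))
  expect_equal(pp$pR2t, unname(sim$observables[2, "pR2t"]), tolerance = 1e-8)
  # higher HER2 at equal HER1/HER3 drives higher HER3 activation
  pair <- her_panel_predict(truth_params, her_panel_fixture()[1:2, ])
  expect_gt(pair$pR3t[2], pair$pR3t[1])
})
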