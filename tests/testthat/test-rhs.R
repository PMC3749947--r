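test_that("compiled RHS equals the stoichiometric-matrix formulation", {
  # independent route: S %*% v assembled from the reaction list in R
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    state <- setNames(runif(51) * 1e4, her_state_names())
    d_net <- her_rhs(state, truth_params, method = "network")
    d_c <- her_rhs(state, truth_params, method = "compiled")
    rel <- max(abs(d_net - d_c)) / max(1, max(abs(d_net)))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-12)
})

test_that("kinetically silent model on a surface-only state is static", {
  p <- silent_params()
  state <- setNames(numeric(51), her_state_names())
  state[paste0(c("R1", "R2", "R3", "R11E", "R22"), "_s")] <- c(1e5, 2e4, 3e3, 10, 5)
  expect_equal(unname(her_rhs(state, p, method = "compiled")),
               rep(0, 51))
  expect_equal(unname(her_rhs(state, p, method = "network")),
               rep(0, 51))
})

test_that("invalid states are rejected", {
  expect_error(her_rhs(rep(1, 50), truth_params), "length")
  st <- rep(1, 51); st[3] <- NA
  expect_error(her_rhs(st, truth_params), "NA")
  st <- rep(1, 51); st[3] <- -1
  expect_error(her_rhs(st, truth_params), "nonnegative")
})

test_that("HER1-only submodel is closed: absent receptors stay absent", {
  prof <- her_profile("her1only", her1 = 2e5, her2 = 0, her3 = 0)
  sim <- her_simulate(truth_params, prof, egf_ng_ml = 30,
                      times = c(0, 30, 120))
  sp <- her_species()
  her23_species <- sp$name[sp$n2 + sp$n3 > 0]
  cols <- unlist(lapply(c("s", "e", "l"),
                        function(cp) paste0(her23_species, "_", cp)))
  expect_true(all(sim$states[, cols] == 0))
  # HRG ligand also never appears
  expect_true(all(sim$states[, c("H_s", "H_e", "H_l")] == 0))
})

test_that("receptor mass balances: d/dt(total) = synthesis - degradation", {
  # algebraic identity checked at random states: summing the RHS with
  # receptor copy weights must give synthesis minus LE degradation flux
  p <- truth_params
  p$synthesis <- c(R1 = 120, R2 = 35, R3 = 8)
  sp <- her_species()
  tr <- herdimer:::.species_trafficking(p)
  for (i in 1:20) {
    state <- random_state(i)
    d <- her_rhs(state, p, method = "compiled")
    le <- state[34 + seq_len(17)]
    deg <- c(R1 = sum(sp$n1 * tr$kd * le), R2 = sum(sp$n2 * tr$kd * le),
             R3 = sum(sp$n3 * tr$kd * le))
    dtot <- her_receptor_totals(d)
    expect_equal(dtot, p$synthesis - deg, tolerance = 1e-10)
  }
})
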