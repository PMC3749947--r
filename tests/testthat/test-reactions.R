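test_that("the reaction network has the expected structure", {
  rx <- her_reactions(truth_params)
  expect_equal(nrow(rx), 76L)
  expect_setequal(unique(rx$compartment), c("s", "e"))
  # 10 dimer types with free dissociation rates per reactive compartment
  off <- rx[rx$class == "dimer_off", ]
  expect_equal(sum(off$compartment == "s"), 10L)
  expect_equal(sum(off$compartment == "e"), 10L)
  expect_equal(length(unique(off$rate_name)), 20L)
  expect_true(all(grepl("^ku", off$rate_name)))
  # dimerization uses the single shared forward rate
  on <- rx[rx$class == "dimer_on", ]
  expect_equal(length(unique(on$rate[on$compartment == "s"])), 1L)
})

test_that("no reactions exist in the late endosome", {
  expect_error(her_reactions(truth_params, compartments = c("s", "l")),
               "late endosome")
})

test_that("mass-action flux matches hand evaluation", {
  # R1E + R2 -> R12E at kc = 0.5 with [R1E] = 2, [R2] = 3 gives flux 3.0
  p <- her_parameters(kc = c(s = 0.5, e = 0.5))
  rx <- her_reactions(p)
  j <- which(rx$class == "dimer_on" & rx$r1 == "R1E" & rx$r2 == "R2" &
               rx$compartment == "s")
  state <- setNames(numeric(51), her_state_names())
  state["R1E_s"] <- 2
  state["R2_s"] <- 3
  v <- herdimer:::.reaction_flux(rx, state)
  expect_equal(v[j], 3.0)
})

test_that("every reaction conserves receptors and total ligand", {
  rx <- her_reactions(truth_params)
  sp <- her_species()
  count <- function(names, col) {
    names <- names[!is.na(names)]
    sum(sp[[col]][match(names, sp$name)])
  }
  for (j in seq_len(nrow(rx))) {
    r <- unlist(rx[j, c("r1", "r2")])
    p <- unlist(rx[j, c("p1", "p2", "p3")])
    for (col in c("n1", "n2", "n3", "nE", "nH"))
      expect_equal(count(r, col), count(p, col),
                   label = paste("reaction", j, col))
  }
})

test_that("context-dependent affinities are exact Kd ratios", {
  kd <- her_kd_table(truth_params)
  expect_equal(kd[["kd_egf_monomer"]] / kd[["kd_egf_r12"]], 1.6)
  expect_equal(kd[["kd_hrg_monomer"]] / kd[["kd_hrg_r23"]], 25)
  expect_equal(kd[["kd_egf_r13h"]] / kd[["kd_egf_monomer"]], 3)
})

test_that("sole-ligand loss collapses the dimer to free monomers", {
  rx <- her_reactions(truth_params)
  col <- rx[rx$class == "ligand_off_collapse", ]
  sp <- her_species()
  for (j in seq_len(nrow(col))) {
    prods <- unlist(col[j, c("p1", "p2", "p3")])
    kinds <- sp$kind[match(prods, sp$name)]
    expect_equal(sort(kinds), c("ligand", "monomer", "monomer"))
  }
  # no ligand-free R11/R12/R13/R33 dimer is ever produced
  made <- unique(unlist(rx[, c("p1", "p2", "p3")]))
  expect_false(any(c("R11", "R12", "R13", "R23", "R33") %in% made))
})
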