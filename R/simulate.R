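# Ligand-stimulation simulation and ELISA-equivalent observables.

#' Simulate a ligand-stimulation protocol
#'
#' Integrates the model from the pre-stimulation steady state of a cell
#' line through a ligand-stimulation protocol and returns the trajectory
#' together with the ELISA-equivalent observables.  Ligand doses in ng/ml
#' are converted to nM using the configured molecular weights and the
#' extracellular concentration is held constant over the protocol.
#'
#' The 2C4/pertuzumab blocking mode (`block_fraction > 0`) removes the
#' given fraction of cellular HER2 from the dimerization-competent pool:
#' the reactive simulation runs with `(1 - block_fraction)` of the nominal
#' HER2 expression (initial condition and synthesis feed), while the
#' sequestered HER2 still traffics at monomer rates and therefore still
#' contributes its (constant, monomeric steady-state) copies to the
#' `mR2t` mass observable, but never to phosphorylation.
#'
#' @param params A [her_parameters()] object.
#' @param profile A cell-line profile (see [her_profile()]).
#' @param egf_ng_ml,hrg_ng_ml Ligand doses (>= 0), ng/ml.
#' @param times Sample times in minutes (nonnegative, increasing); `t = 0`
#'   reports the pre-stimulation steady state.
#' @param block_fraction Fraction of HER2 sequestered by 2C4, in `[0, 1]`.
#' @param equilibrium Optionally a precomputed [her_equilibrate()] result
#'   for the (blocked) profile, to skip re-equilibration.
#' @param rtol,atol Integrator tolerances (stiff-capable `lsoda`).
#' @return An object of class `her_sim`: list with `times`, `states`
#'   (time x 51 matrix), `observables` (time x 9 matrix with columns
#'   `pR1t..pR3t`, `pR1i..pR3i`, `mR1t..mR3t`), the protocol fields and
#'   the parameter set used.
#' @export
her_simulate <- function(params, profile,
                         egf_ng_ml = 0, hrg_ng_ml = 0,
                         times = seq(0, 120, by = 5),
                         block_fraction = 0,
                         equilibrium = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "her_parameters"))
  if (egf_ng_ml < 0 || hrg_ng_ml < 0) stop("ligand doses must be >= 0")
  if (block_fraction < 0 || block_fraction > 1)
    stop("block_fraction must lie in [0, 1]")
  if (is.unsorted(times, strictly = FALSE) || any(times < 0))
    stop("times must be nonnegative and increasing")

  blocked <- her_apply_block(profile, block_fraction)
  if (is.null(equilibrium)) {
    equilibrium <- her_equilibrate(blocked$available, params)
  }
  params <- equilibrium$params
  state0 <- equilibrium$state
  state0[.state_index("E", "s")] <-
    egf_ng_ml / params$ligand_mw_kda[["egf"]]
  state0[.state_index("H", "s")] <-
    hrg_ng_ml / params$ligand_mw_kda[["hrg"]]

  tt <- unique(c(0, times))
  sol <- .integrate_states(state0, params, times = tt,
                           rtol = rtol, atol = atol)
  keep <- match(times, sol[, 1L])
  states <- sol[keep, -1L, drop = FALSE]
  colnames(states) <- her_state_names()
  rownames(states) <- NULL
  # integrator round-off can leave tiny negative values
  states[states < 0 & states > -atol * 10] <- 0

  seq_mass <- 0
  if (block_fraction > 0) {
    tr2 <- .monomer_rates(params, "R2")
    ms <- .monomer_steady(blocked$sequestered_her2,
                          tr2$kint, tr2$kr, tr2$kl, tr2$kd)
    seq_mass <- ms$s + ms$e + ms$l
  }
  obs <- her_observables(states, params, extra_mass = c(R2 = seq_mass))
  structure(list(
    times = times, states = states, observables = obs,
    profile = profile, egf_ng_ml = egf_ng_ml, hrg_ng_ml = hrg_ng_ml,
    block_fraction = block_fraction, params = params
  ), class = "her_sim")
}

#' Sequester HER2 from the dimerization-competent pool
#'
#' Models saturating 2C4 (pertuzumab) as irreversible removal of a
#' fraction of cellular HER2 from the reactive pool; the antibody
#' concentration used experimentally is far above the 2C4-HER2 Kd, so
#' explicit binding kinetics are not modelled.
#'
#' @param profile A cell-line profile.
#' @param fraction Fraction of HER2 made unavailable, in `[0, 1]`.
#' @return A list with `available` (profile with HER2 scaled to
#'   `1 - fraction` of nominal) and `sequestered_her2` (copies/cell that
#'   still count toward `mR2t`).
#' @export
her_apply_block <- function(profile, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single number in [0, 1]", call. = FALSE)
  avail <- profile
  avail$her2 <- profile$her2 * (1 - fraction)
  list(available = avail, sequestered_her2 = profile$her2 * fraction)
}

#' Map dimer species to phosphorylation factors
#'
#' The linear readout converting dimer abundances to receptor
#' phosphorylation signals: for each receptor and contributing dimer the
#' surface (`pf_s`) and early-endosome (`pf_i`) factor names.  HER3
#' homodimers contribute nothing to pR3 (HER3 is kinase-dead; their pf is
#' identically zero) and appear with `NA` factor names.
#'
#' @return A data.frame with columns `receptor`, `dimer`, `pf_s`, `pf_i`.
#' @export
her_pf_map <- function() {
  data.frame(
    receptor = c(rep("R1", 6), rep("R2", 3), rep("R3", 6)),
    dimer = c("R11E", "R11EE", "R12E", "R13E", "R13H", "R13EH",
              "R12E", "R22", "R23H",
              "R13E", "R13H", "R13EH", "R23H", "R33H", "R33HH"),
    pf_s = c("pf11es", "pf11ees", "pf12es", "pf13es", "pf13hs", "pf13ehs",
             "pf21es", "pf22s", "pf23hs",
             "pf31es", "pf31hs", "pf31ehs", "pf32hs", NA, NA),
    pf_i = c("pf11ei", "pf11eei", "pf12ei", "pf13ei", "pf13hi", "pf13ehi",
             "pf21ei", "pf22i", "pf23hi",
             "pf31ei", "pf31hi", "pf31ehi", "pf32hi", NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Compute ELISA-equivalent observables from a trajectory
#'
#' For each receptor `i`: the surface phospho-signal is the pf-weighted
#' sum of surface dimer abundances, the internal signal (`pRii`) the
#' pf-weighted sum over the early endosome, `pRit` their sum, and `mRit`
#' the total receptor copies over all three compartments (homodimer
#' members counted twice).  Late-endosome species contribute to mass
#' only.
#'
#' @param states Matrix (rows = times) or named vector of model states.
#' @param params A [her_parameters()] object supplying the pf table.
#' @param extra_mass Named vector of constant extra receptor copies to add
#'   to the mass observables (used for sequestered HER2).
#' @return A matrix with columns `pR1t`, `pR2t`, `pR3t`, `pR1i`, `pR2i`,
#'   `pR3i`, `mR1t`, `mR2t`, `mR3t`.
#' @export
her_observables <- function(states, params,
                            extra_mass = c(R1 = 0, R2 = 0, R3 = 0)) {
  stopifnot(inherits(params, "her_parameters"))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1,
                                             dimnames = list(NULL, names(states)))
  w <- .obs_weights(params)
  pint <- states %*% w$P_int
  ptot <- states %*% w$P_surf + pint
  mass <- states %*% w$M
  for (rec in intersect(names(extra_mass), c("R1", "R2", "R3")))
    mass[, match(rec, c("R1", "R2", "R3"))] <-
      mass[, match(rec, c("R1", "R2", "R3"))] + extra_mass[[rec]]
  out <- cbind(ptot, pint, mass)
  colnames(out) <- c("pR1t", "pR2t", "pR3t", "pR1i", "pR2i", "pR3i",
                     "mR1t", "mR2t", "mR3t")
  out
}

# 51 x 3 weight matrices for the linear readout: pf-weighted surface and
# EE dimer abundances (phospho) and receptor copy counts (mass); index
# structure is static, pf values come from the parameter set
.obs_weights <- function(params) {
  if (is.null(.cache$obs_idx)) {
    pm <- her_pf_map()
    pm <- pm[!is.na(pm$pf_s), ]
    sp <- .species_table()
    .cache$obs_idx <- list(
      pm = pm,
      rec = match(pm$receptor, c("R1", "R2", "R3")),
      idx_s = .state_index(pm$dimer, "s"),
      idx_e = .state_index(pm$dimer, "e"),
      M = local({
        M <- matrix(0, .n_state, 3)
        for (ci in 0:2)
          M[ci * .n_species + seq_len(.n_species), ] <-
            cbind(sp$n1, sp$n2, sp$n3)
        M
      })
    )
  }
  oi <- .cache$obs_idx
  miss <- setdiff(c(oi$pm$pf_s, oi$pm$pf_i), names(params$pf))
  if (length(miss) > 0)
    stop("missing pf entry: ", paste(miss, collapse = ", "), call. = FALSE)
  P_surf <- matrix(0, .n_state, 3)
  P_int <- matrix(0, .n_state, 3)
  P_surf[cbind(oi$idx_s, oi$rec)] <- unname(params$pf[oi$pm$pf_s])
  P_int[cbind(oi$idx_e, oi$rec)] <- unname(params$pf[oi$pm$pf_i])
  list(P_surf = P_surf, P_int = P_int, M = oi$M)
}

#' @export
print.her_sim <- function(x, ...) {
  cat(sprintf(
    "HER activation simulation: '%s', EGF %g ng/ml, HRG %g ng/ml%s\n",
    x$profile$name, x$egf_ng_ml, x$hrg_ng_ml,
    if (x$block_fraction > 0)
      sprintf(", 2C4 block %.0f%%", 100 * x$block_fraction) else ""))
  cat(sprintf("  %d sample times in [%g, %g] min\n",
              length(x$times), min(x$times), max(x$times)))
  last <- x$observables[nrow(x$observables), ]
  cat(sprintf("  at t = %g min:  pR1t %.3g  pR2t %.3g  pR3t %.3g\n",
              max(x$times), last[["pR1t"]], last[["pR2t"]], last[["pR3t"]]))
  invisible(x)
}

#' Extract observables from a simulation in tidy form
#'
#' @param sim A `her_sim` object.
#' @return A data.frame with columns `time_min`, `measurement`, `value`.
#' @export
her_sim_tidy <- function(sim) {
  stopifnot(inherits(sim, "her_sim"))
  obs <- sim$observables
  data.frame(
    time_min = rep(sim$times, times = ncol(obs)),
    measurement = rep(colnames(obs), each = length(sim$times)),
    value = as.vector(obs),
    stringsAsFactors = FALSE
  )
}
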