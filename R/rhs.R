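# ODE right-hand side.
#
# Two equivalent formulations are provided: a compiled C right-hand side
# (src/her_rhs.c) used for all integrations, and an R formulation built
# from the assembled reaction list as S %*% v plus linear trafficking.
# The two are cross-checked against each other in the test suite; the
# network route also serves spec'd structural queries (reaction counts,
# stoichiometry).
#
# The derivative combines: reaction fluxes at the surface and early
# endosome; internalization (kt for monomers, ke for dimers); recycling
# and late-endosome entry out of the early endosome; degradation from the
# late endosome; constant synthesis of the three receptor monomers at the
# surface.  The late endosome carries no biochemistry, and extracellular
# free ligand is clamped to the stimulation protocol (no depletion).

# order of the parameter vector handed to the compiled code; must match
# src/her_rhs.c
.build_parms <- function(params) {
  b <- params$binding
  vol <- params$ee_volume_factor
  tr <- .species_trafficking(params)
  ku_s <- unname(params$ku[paste0("ku", .dimer_tags, "s")])
  ku_e <- unname(params$ku[paste0("ku", .dimer_tags, "i")])
  c(b$kon1s, b$koff1s, b$kon3s, b$koff3s,
    b$kon1e * vol, b$koff1e, b$kon3e * vol, b$koff3e,
    params$kc[["s"]], params$kc[["e"]] * vol,
    ku_s, ku_e,
    params$affinity_fold[["r12_egf"]],
    params$affinity_fold[["r23_hrg"]],
    params$affinity_fold[["r13_hrg_egf"]],
    tr$kint, tr$kr, tr$kl, tr$kd,
    unname(params$synthesis[c("R1", "R2", "R3")]))
}

#' Evaluate the model right-hand side
#'
#' Computes the time derivative of the 51-dimensional state under a given
#' parameter set.  `method = "compiled"` calls the C implementation through
#' deSolve's single-step evaluator; `method = "network"` assembles the
#' derivative independently as stoichiometric matrix times mass-action
#' flux vector from [her_reactions()] plus the linear trafficking and
#' synthesis terms.  Both clamp the surface free-ligand derivatives to
#' zero (ligand depletion from the medium is ignored).
#'
#' @param state Numeric state vector of length 51 (nonnegative).
#' @param params A [her_parameters()] object.
#' @param method `"compiled"` or `"network"`.
#' @return Named derivative vector of length 51.
#' @export
her_rhs <- function(state, params, method = c("network", "compiled")) {
  method <- match.arg(method)
  if (length(state) != .n_state)
    stop("state must have length ", .n_state, call. = FALSE)
  if (anyNA(state) || any(!is.finite(state)))
    stop("state contains NA or non-finite values", call. = FALSE)
  if (any(state < 0))
    stop("state must be nonnegative", call. = FALSE)
  if (method == "network") {
    rx <- her_reactions(params)
    S <- her_stoichiometry(rx)
    v <- .reaction_flux(rx, state)
    d <- as.vector(S %*% v)
    tr <- .species_trafficking(params)
    i_s <- seq_len(.n_species)
    i_e <- i_s + .n_species
    i_l <- i_s + 2L * .n_species
    d[i_s] <- d[i_s] - tr$kint * state[i_s] + tr$kr * state[i_e]
    d[i_e] <- d[i_e] + tr$kint * state[i_s] - (tr$kr + tr$kl) * state[i_e]
    d[i_l] <- d[i_l] + tr$kl * state[i_e] - tr$kd * state[i_l]
    d[.state_index(c("R1", "R2", "R3"), "s")] <-
      d[.state_index(c("R1", "R2", "R3"), "s")] +
      unname(params$synthesis[c("R1", "R2", "R3")])
    d[.state_index(c("E", "H"), "s")] <- 0
    names(d) <- her_state_names()
    d
  } else {
    out <- .rhs_compiled_eval(state, params)
    names(out) <- her_state_names()
    out
  }
}

# single evaluation of the compiled derivs
.rhs_compiled_eval <- function(state, params) {
  parms <- .build_parms(params)
  ev <- deSolve::DLLfunc(y = unname(state), dllname = "herdimer",
                         func = "derivs", initfunc = "initparms",
                         times = 0, parms = parms)
  ev$dy
}
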