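# Reaction network assembly.
#
# Biochemical reactions (ligand binding/unbinding, dimerization and
# dissociation) occur at the cell surface and in the early endosome only.
# Dimerization requires at least one ligand-bound partner, except the
# constitutive HER2 homodimerization R2 + R2 <-> R22; ligand-free
# HER1/HER3-containing dimers never exist.  Loss of the sole ligand from a
# singly-liganded dimer destabilizes it instantly and is lumped into a
# single collapse event yielding two free monomers.

#' Build the reaction list of the HER network
#'
#' Enumerates every mass-action reaction of the model in the two reactive
#' compartments, resolving each reaction's rate constant from the supplied
#' parameter set.  Per compartment there are 6 ligand-association, 6
#' ligand-dissociation, 6 lumped ligand-loss-with-dimer-collapse, 10
#' dimerization and 10 dimer-dissociation reactions (38; 76 in total).
#' The 10 dimer dissociation rates per compartment (20 overall) are the
#' free `ku` parameters.
#'
#' Context-dependent affinities enter through off-rates: EGF leaves the
#' R12E dimer at `koff1/1.6`, HRG leaves R23H at `koff3/25`, and EGF leaves
#' (or collapses from) an HRG-occupied R13 dimer at `3*koff1`.  Doubly
#' liganded symmetric dimers (R11EE, R33HH) carry a statistical factor of 2
#' on single-ligand loss.
#'
#' @param params A [her_parameters()] object.
#' @param compartments Compartments to build; must be a subset of
#'   `c("s", "e")`.  Requesting the late endosome is an error: it carries
#'   no biochemistry.
#' @return A data.frame with one row per reaction: `compartment`, `class`
#'   (`ligand_on`, `ligand_off`, `ligand_off_collapse`, `dimer_on`,
#'   `dimer_off`), reactants `r1`, `r2` (`NA` for unimolecular), products
#'   `p1`..`p3`, `rate_name` and the numeric `rate`.
#' @export
her_reactions <- function(params = her_parameters(),
                          compartments = c("s", "e")) {
  stopifnot(inherits(params, "her_parameters"))
  if (any(compartments == "l"))
    stop("the late endosome carries no biochemical reactions", call. = FALSE)
  bad <- setdiff(compartments, c("s", "e"))
  if (length(bad) > 0)
    stop("unknown compartment(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  b <- params$binding
  af <- params$affinity_fold
  vol <- params$ee_volume_factor
  rows <- list()
  add <- function(comp, class, r1, r2, p1, p2, p3, rate_name, rate) {
    rows[[length(rows) + 1L]] <<- data.frame(
      compartment = comp, class = class, r1 = r1, r2 = r2,
      p1 = p1, p2 = p2, p3 = p3,
      rate_name = rate_name, rate = rate, stringsAsFactors = FALSE)
  }
  for (comp in compartments) {
    ee <- comp == "e"
    kon1 <- if (ee) b$kon1e * vol else b$kon1s
    koff1 <- if (ee) b$koff1e else b$koff1s
    kon3 <- if (ee) b$kon3e * vol else b$kon3s
    koff3 <- if (ee) b$koff3e else b$koff3s
    kc <- if (ee) params$kc[["e"]] * vol else params$kc[["s"]]
    sfx <- if (ee) "i" else "s"
    kn <- function(base) paste0(base, sfx)

    # ligand association
    add(comp, "ligand_on", "E", "R1", "R1E", NA, NA, kn("kon1"), kon1)
    add(comp, "ligand_on", "H", "R3", "R3H", NA, NA, kn("kon3"), kon3)
    add(comp, "ligand_on", "E", "R11E", "R11EE", NA, NA, kn("kon1"), kon1)
    add(comp, "ligand_on", "H", "R33H", "R33HH", NA, NA, kn("kon3"), kon3)
    add(comp, "ligand_on", "E", "R13H", "R13EH", NA, NA, kn("kon1"), kon1)
    add(comp, "ligand_on", "H", "R13E", "R13EH", NA, NA, kn("kon3"), kon3)
    # ligand dissociation leaving a stable complex behind
    add(comp, "ligand_off", "R1E", NA, "E", "R1", NA, kn("koff1"), koff1)
    add(comp, "ligand_off", "R3H", NA, "H", "R3", NA, kn("koff3"), koff3)
    add(comp, "ligand_off", "R11EE", NA, "E", "R11E", NA,
        kn("2koff1"), 2 * koff1)
    add(comp, "ligand_off", "R33HH", NA, "H", "R33H", NA,
        kn("2koff3"), 2 * koff3)
    add(comp, "ligand_off", "R13EH", NA, "E", "R13H", NA,
        kn("3koff1"), af[["r13_hrg_egf"]] * koff1)
    add(comp, "ligand_off", "R13EH", NA, "H", "R13E", NA, kn("koff3"), koff3)
    # loss of the sole ligand collapses the dimer into free monomers
    add(comp, "ligand_off_collapse", "R11E", NA, "E", "R1", "R1",
        kn("koff1"), koff1)
    add(comp, "ligand_off_collapse", "R12E", NA, "E", "R1", "R2",
        kn("koff1/1.6"), koff1 / af[["r12_egf"]])
    add(comp, "ligand_off_collapse", "R13E", NA, "E", "R1", "R3",
        kn("koff1"), koff1)
    add(comp, "ligand_off_collapse", "R13H", NA, "H", "R1", "R3",
        kn("koff3"), koff3)
    add(comp, "ligand_off_collapse", "R23H", NA, "H", "R2", "R3",
        kn("koff3/25"), koff3 / af[["r23_hrg"]])
    add(comp, "ligand_off_collapse", "R33H", NA, "H", "R3", "R3",
        kn("koff3"), koff3)
    # dimerization at the common diffusion-limited forward rate
    add(comp, "dimer_on", "R1E", "R1", "R11E", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R1E", "R1E", "R11EE", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R1E", "R2", "R12E", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R1E", "R3", "R13E", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R1", "R3H", "R13H", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R1E", "R3H", "R13EH", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R2", "R2", "R22", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R2", "R3H", "R23H", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R3", "R3H", "R33H", NA, NA, kn("kc"), kc)
    add(comp, "dimer_on", "R3H", "R3H", "R33HH", NA, NA, kn("kc"), kc)
    # dimer dissociation (free ku rates)
    ud <- data.frame(
      dimer = c("R11E", "R11EE", "R12E", "R13E", "R13H", "R13EH",
                "R22", "R23H", "R33H", "R33HH"),
      m1 = c("R1E", "R1E", "R1E", "R1E", "R1", "R1E",
             "R2", "R2", "R3", "R3H"),
      m2 = c("R1", "R1E", "R2", "R3", "R3H", "R3H",
             "R2", "R3H", "R3H", "R3H"),
      stringsAsFactors = FALSE)
    kunames <- paste0("ku", .dimer_tags, sfx)
    for (i in seq_len(nrow(ud))) {
      add(comp, "dimer_off", ud$dimer[i], NA, ud$m1[i], ud$m2[i], NA,
          kunames[i], params$ku[[kunames[i]]])
    }
  }
  rx <- do.call(rbind, rows)
  known <- her_species()$name
  used <- unique(stats::na.omit(unlist(rx[, c("r1", "r2", "p1", "p2", "p3")])))
  if (length(setdiff(used, known)) > 0)
    stop("reaction references unknown species: ",
         paste(setdiff(used, known), collapse = ", "))
  rx
}

#' Stoichiometric matrix of the assembled network
#'
#' Net stoichiometry of every reaction over the 51-dimensional state
#' vector.  Homodimerization reactions (identical reactants) consume two
#' copies of the reactant; collapse and symmetric dissociation reactions
#' produce two copies where the products coincide.
#'
#' @param reactions Output of [her_reactions()].
#' @return A 51 x nrow(reactions) numeric matrix with state names as row
#'   names.
#' @export
her_stoichiometry <- function(reactions) {
  S <- matrix(0, nrow = .n_state, ncol = nrow(reactions),
              dimnames = list(her_state_names(), NULL))
  for (j in seq_len(nrow(reactions))) {
    comp <- reactions$compartment[j]
    for (r in stats::na.omit(c(reactions$r1[j], reactions$r2[j])))
      S[.state_index(r, comp), j] <- S[.state_index(r, comp), j] - 1
    for (p in stats::na.omit(c(reactions$p1[j], reactions$p2[j],
                               reactions$p3[j])))
      S[.state_index(p, comp), j] <- S[.state_index(p, comp), j] + 1
  }
  S
}

# Mass-action flux vector for a state: v_j = k_j * x_r1 * x_r2 (bimolecular,
# with x_r1^2 for identical reactants) or k_j * x_r1 (unimolecular).
.reaction_flux <- function(reactions, state) {
  v <- numeric(nrow(reactions))
  for (j in seq_len(nrow(reactions))) {
    comp <- reactions$compartment[j]
    x1 <- state[.state_index(reactions$r1[j], comp)]
    v[j] <- reactions$rate[j] * x1
    if (!is.na(reactions$r2[j]))
      v[j] <- v[j] * state[.state_index(reactions$r2[j], comp)]
  }
  v
}
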