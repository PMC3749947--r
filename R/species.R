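# Species enumeration for the HER1-3 activation network.
#
# The network tracks 17 molecular species: the two ligands EGF (E) and
# heregulin (H), five receptor monomers (ligand-free and ligand-bound), and
# the ten dimer types that can form after ligand addition.  Every species
# exists in three cellular compartments (cell surface "s", early endosome
# "e", late endosome "l"), giving a 51-dimensional state vector.

#' Enumerate the model species
#'
#' Returns the canonical species table of the HER activation network: the
#' ligands EGF (`E`) and HRG (`H`); the monomers `R1`, `R1E`, `R2`, `R3`,
#' `R3H`; and the ten dimers `R11E`, `R11EE`, `R12E`, `R13E`, `R13H`,
#' `R13EH`, `R22`, `R23H`, `R33H`, `R33HH`.  Species names follow the `Rij`
#' convention where `i`, `j` are the HER types in the complex and trailing
#' `E`/`H` letters give the bound-ligand occupancy.  The row order of this
#' table is the canonical state-vector layout (species-minor within each
#' compartment); it never depends on expression levels, which only set
#' initial conditions.
#'
#' Occupancy is constrained by receptor biology: HER2 has no ligand, HER3
#' cannot bind EGF, and HER1 cannot bind HRG.  Ligand-free HER1/HER3 dimers
#' are absent by construction (basal dimerization is neglected), while the
#' HER2 homodimer `R22` forms constitutively.
#'
#' @param receptors Character vector of modelled receptors.  Only
#'   `c("HER1", "HER2", "HER3")` is supported; anything else is an error.
#' @param ligands Character vector of modelled ligands, a subset of
#'   `c("EGF", "HRG")`.  This restricts which species can ever be populated
#'   but does not change the species list (the state layout is frozen).
#'
#' @return A data.frame with one row per species and columns `name`, `kind`
#'   (`"ligand"`, `"monomer"` or `"dimer"`), receptor copy numbers `n1`,
#'   `n2`, `n3`, ligand occupancies `nE`, `nH`, and the trafficking class
#'   `traffic_class` (`"ligand"`, `"her1"` for pure-HER1 species, `"her23"`
#'   for species containing HER2 or HER3).
#' @export
#' @examples
#' sp <- her_species()
#' nrow(sp)                       # 17
#' sum(sp$kind == "dimer")       # 10
her_species <- function(receptors = c("HER1", "HER2", "HER3"),
                        ligands = c("EGF", "HRG")) {
  allowed <- c("HER1", "HER2", "HER3")
  bad <- setdiff(receptors, allowed)
  if (length(bad) > 0L) {
    stop("unsupported receptor(s): ", paste(bad, collapse = ", "),
         "; the model covers HER1, HER2 and HER3 only", call. = FALSE)
  }
  bad_lig <- setdiff(ligands, c("EGF", "HRG"))
  if (length(bad_lig) > 0L) {
    stop("unsupported ligand(s): ", paste(bad_lig, collapse = ", "),
         call. = FALSE)
  }
  sp <- data.frame(
    name = c("E", "H", "R1", "R1E", "R2", "R3", "R3H",
             "R11E", "R11EE", "R12E", "R13E", "R13H", "R13EH",
             "R22", "R23H", "R33H", "R33HH"),
    kind = c("ligand", "ligand", rep("monomer", 5L), rep("dimer", 10L)),
    n1 = c(0, 0, 1, 1, 0, 0, 0, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0),
    n2 = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 2, 1, 0, 0),
    n3 = c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1, 1, 0, 1, 2, 2),
    nE = c(1, 0, 0, 1, 0, 0, 0, 1, 2, 1, 1, 0, 1, 0, 0, 0, 0),
    nH = c(0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 1, 1, 2),
    stringsAsFactors = FALSE
  )
  sp$traffic_class <- ifelse(
    sp$kind == "ligand", "ligand",
    ifelse(sp$n2 + sp$n3 > 0, "her23", "her1")
  )
  sp
}

#' Compartments of the trafficking model
#'
#' @return Character vector `c("s", "e", "l")`: cell surface, early
#'   endosome, late endosome.  Biochemical reactions occur in `s` and `e`
#'   only; the late endosome is a degradation staging compartment.
#' @export
her_compartments <- function() c("s", "e", "l")

#' Canonical state-vector names
#'
#' Compartment-major, species-minor layout: all 17 surface species, then
#' all 17 early-endosome species, then all 17 late-endosome species, for a
#' total of 51 state variables.
#'
#' @return Character vector of length 51, e.g. `"R1E_s"`, `"R22_e"`.
#' @export
her_state_names <- function() {
  sp <- her_species()$name
  as.vector(vapply(her_compartments(),
                   function(cp) paste0(sp, "_", cp),
                   character(length(sp))))
}

# internal index helpers (1-based); static tables are cached at load time
.n_species <- 17L
.n_state <- 51L

.cache <- new.env(parent = emptyenv())

.species_table <- function() {
  if (is.null(.cache$species)) .cache$species <- her_species()
  .cache$species
}

.species_names <- function() .species_table()$name

.sp_index <- function(name) {
  i <- match(name, .species_names())
  if (anyNA(i)) stop("unknown species: ", paste(name[is.na(i)], collapse = ", "))
  i
}

# index of species `name` in compartment `comp` within the 51-state vector
.state_index <- function(name, comp) {
  ci <- match(comp, her_compartments())
  (ci - 1L) * .n_species + .sp_index(name)
}
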