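# Parameter sets: rate constants, phosphorylation factors and trafficking
# constants for the HER activation model.
#
# The free/fixed partition follows the estimation problem: the 20
# compartment-specific dimer dissociation rates (ku), the 26 phosphorylation
# factors (pf) and the sorting parameter delta1 are free (47 parameters);
# everything else (ligand binding kinetics, the common dimerization forward
# rate kc, trafficking constants, ligand molecular weights) is fixed from
# literature-range values.

.dimer_tags <- c("11e", "11ee", "12e", "13e", "13h", "13eh",
                 "22", "23h", "33h", "33hh")

.ku_names <- function() {
  c(paste0("ku", .dimer_tags, "s"), paste0("ku", .dimer_tags, "i"))
}

.pf_tags <- c("11es", "11ees", "12es", "13es", "13hs", "13ehs",
              "21es", "22s", "23hs", "32hs", "31es", "31hs", "31ehs")

.pf_names <- function() {
  # surface set keeps the literal "s" suffix; the early-endosome set swaps
  # the trailing s for i (pf11ees -> pf11eei), matching the pf<ijc> notation
  c(paste0("pf", .pf_tags),
    paste0("pf", sub("s$", "i", .pf_tags)))
}

# default free-parameter values; these double as the shipped ground truth
# for the synthetic-data generator.  pf11ees = 0.03 sits in the
# independently reported range for doubly-EGF-bound HER1 homodimers.  The
# R11/R12 dissociation rates are on the same scale as the competing loss
# processes (ligand loss ~0.5/min, dimer internalization 0.2/min), which
# is what makes them practically identifiable from dose-response data;
# R11 remains more stable than R12.  R23 is strong and slow to
# dissociate; R13/R33 are weak and fast-cycling.
.default_ku <- c(
  ku11es = 0.60, ku11ees = 0.30, ku12es = 1.00, ku13es = 0.50,
  ku13hs = 0.40, ku13ehs = 0.10, ku22s = 10.0, ku23hs = 0.05,
  ku33hs = 2.00, ku33hhs = 1.00,
  ku11ei = 1.20, ku11eei = 0.60, ku12ei = 2.00, ku13ei = 1.00,
  ku13hi = 0.80, ku13ehi = 0.20, ku22i = 20.0, ku23hi = 0.10,
  ku33hi = 4.00, ku33hhi = 2.00
)

.default_pf <- c(
  pf11es = 0.015, pf11ees = 0.030, pf12es = 0.450, pf13es = 0.020,
  pf13hs = 0.020, pf13ehs = 0.030, pf21es = 0.200, pf22s = 0.010,
  pf23hs = 0.150, pf32hs = 0.100, pf31es = 0.050, pf31hs = 0.050,
  pf31ehs = 0.080,
  pf11ei = 0.010, pf11eei = 0.020, pf12ei = 0.050, pf13ei = 0.010,
  pf13hi = 0.010, pf13ehi = 0.015, pf21ei = 0.100, pf22i = 0.005,
  pf23hi = 0.080, pf32hi = 0.050, pf31ei = 0.025, pf31hi = 0.025,
  pf31ehi = 0.040
)

#' Assemble a model parameter set
#'
#' Builds the complete parameter set of the HER activation model.  Defaults
#' are a versioned, self-consistent configuration: ligand binding kinetics
#' and trafficking constants are fixed at human-mammary-epithelial
#' literature-range values, and the 47 free parameters (20 `ku`, 26 `pf`,
#' `delta1`) default to the shipped ground-truth values used by the
#' synthetic-data generator.
#'
#' Units: receptor abundances are molecules/cell; extracellular ligand is
#' nM (converted from ng/ml via the ligand molecular weights); first-order
#' rates are min^-1; ligand on-rates are nM^-1 min^-1; the dimerization
#' forward rate `kc` is (molecules/cell)^-1 min^-1.  Early-endosome
#' bimolecular reactions use the same molecules/cell basis scaled by
#' `ee_volume_factor` (default 1).
#'
#' Context-dependent ligand affinities are implemented by scaling the
#' ligand off-rate inside the dimer, so the dissociation-constant ratios
#' hold exactly: EGF binds the HER1-HER2 dimer 60% more strongly than the
#' HER1 monomer (Kd / 1.6), HRG binds the HER2-HER3 dimer 25-fold more
#' strongly than the HER3 monomer (Kd / 25), and a bound HRG weakens EGF
#' binding in the HER1-HER3 dimer 3-fold (Kd x 3).
#'
#' @param ku Named numeric vector of the 20 dimer dissociation rates
#'   (min^-1), names `ku<tag><s|i>` for the cell surface / early endosome.
#' @param pf Named numeric vector of the 26 phosphorylation factors,
#'   names `pf<ijc>` where `i` is the receptor read out, `j` its partner
#'   (plus ligand letters) and `c` in `s`/`i` the compartment.
#' @param delta1 Sorting parameter of the EGFR monomer (> 0): the ratio of
#'   late-endosome entry to exit rates; fixes the recycling/degradation
#'   split of every other species through the sorting chain rule.
#' @param binding Named list of ligand binding kinetics (see defaults).
#' @param kc Length-2 vector `c(s=, e=)`: common diffusion-limited
#'   dimerization forward rate per reactive compartment.
#' @param affinity_fold Length-3 vector of dimer-context affinity factors
#'   `c(r12_egf=1.6, r23_hrg=25, r13_hrg_egf=3)`.
#' @param trafficking List with elements `her1` and `her23`, each
#'   `c(kt=, ke=, kx=, f=)`: internalization rates for monomers (`kt`) and
#'   dimers (`ke`), endosomal exit rate `kx` and recycling fraction `f`.
#'   HER3 species traffic like HER2 species (class `her23`).
#' @param ligand_mw_kda Molecular weights used for ng/ml to nM conversion.
#' @param ee_volume_factor Scaling of early-endosome bimolecular rates.
#' @param synthesis Surface synthesis rates (molecules/cell/min) for the
#'   three receptors; normally solved by [her_equilibrate()].
#'
#' @return An object of class `her_parameters`.
#' @export
#' @examples
#' p <- her_parameters()
#' length(her_free_names())      # 47
her_parameters <- function(ku = .default_ku,
                           pf = .default_pf,
                           delta1 = 2,
                           binding = list(
                             kon1s = 0.097, koff1s = 0.24,
                             kon1e = 0.097, koff1e = 2.0,
                             kon3s = 0.060, koff3s = 0.12,
                             kon3e = 0.097, koff3e = 2.0
                           ),
                           kc = c(s = 1e-4, e = 1e-4),
                           affinity_fold = c(r12_egf = 1.6, r23_hrg = 25,
                                             r13_hrg_egf = 3),
                           trafficking = list(
                             her1 = c(kt = 0.02, ke = 0.20, kx = 0.15, f = 0.50),
                             her23 = c(kt = 0.01, ke = 0.03, kx = 0.15, f = 0.85)
                           ),
                           ligand_mw_kda = c(egf = 6.4, hrg = 7.5),
                           ee_volume_factor = 1,
                           synthesis = c(R1 = 0, R2 = 0, R3 = 0)) {
  ku <- .check_named(ku, .ku_names(), "ku")
  pf <- .check_named(pf, .pf_names(), "pf")
  errs <- character(0)
  if (any(ku < 0)) errs <- c(errs, "all ku rates must be >= 0")
  if (any(pf < 0)) errs <- c(errs, "all pf values must be >= 0")
  z <- grepl("^pf33", names(pf))
  if (any(z) && any(pf[z] != 0))
    errs <- c(errs, "HER3-homodimer pf values must be 0")
  if (!is.numeric(delta1) || length(delta1) != 1L || delta1 <= 0)
    errs <- c(errs, "delta1 must be a single positive number")
  need <- c("kon1s", "koff1s", "kon1e", "koff1e",
            "kon3s", "koff3s", "kon3e", "koff3e")
  miss <- setdiff(need, names(binding))
  if (length(miss) > 0)
    errs <- c(errs, paste0("missing binding rate(s): ",
                           paste(miss, collapse = ", ")))
  for (cl in c("her1", "her23")) {
    tr <- trafficking[[cl]]
    if (is.null(tr) || !all(c("kt", "ke", "kx", "f") %in% names(tr))) {
      errs <- c(errs, paste0("trafficking$", cl,
                             " must supply kt, ke, kx and f"))
    } else {
      if (any(tr[c("kt", "ke", "kx")] < 0))
        errs <- c(errs, paste0("trafficking$", cl, " rates must be >= 0"))
      if (tr[["f"]] < 0 || tr[["f"]] >= 1)
        errs <- c(errs, paste0("trafficking$", cl, " recycling fraction f",
                               " must lie in [0, 1)"))
    }
  }
  if (any(kc < 0) || !all(c("s", "e") %in% names(kc)))
    errs <- c(errs, "kc must be a nonnegative vector with entries s and e")
  if (length(errs) > 0)
    stop("invalid parameter set:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)

  structure(list(
    ku = ku, pf = pf, delta1 = delta1,
    binding = binding, kc = kc,
    affinity_fold = affinity_fold,
    trafficking = trafficking,
    ligand_mw_kda = ligand_mw_kda,
    ee_volume_factor = ee_volume_factor,
    synthesis = synthesis
  ), class = "her_parameters")
}

.check_named <- function(x, expected, what) {
  miss <- setdiff(expected, names(x))
  extra <- setdiff(names(x), expected)
  if (length(miss) > 0 || length(extra) > 0) {
    msg <- character(0)
    if (length(miss) > 0)
      msg <- c(msg, paste0("missing ", what, " entries: ",
                           paste(miss, collapse = ", ")))
    if (length(extra) > 0)
      msg <- c(msg, paste0("unknown ", what, " entries: ",
                           paste(extra, collapse = ", ")))
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  x[expected]
}

#' Names of the 47 free parameters
#'
#' The estimation problem's free set: 20 dimer dissociation rates, 26
#' phosphorylation factors and the sorting parameter `delta1`.
#'
#' @return Character vector of length 47.
#' @export
her_free_names <- function() c(.ku_names(), .pf_names(), "delta1")

#' Extract the free-parameter vector from a parameter set
#' @param params A `her_parameters` object.
#' @return Named numeric vector of length 47.
#' @export
her_free_values <- function(params) {
  stopifnot(inherits(params, "her_parameters"))
  c(params$ku, params$pf, delta1 = params$delta1)[her_free_names()]
}

#' Replace free parameters in a parameter set
#' @param params A `her_parameters` object.
#' @param values Named numeric vector; names must be free-parameter names.
#' @return The updated `her_parameters` object.
#' @export
her_set_free <- function(params, values) {
  stopifnot(inherits(params, "her_parameters"))
  bad <- setdiff(names(values), her_free_names())
  if (length(bad) > 0)
    stop("not free parameters: ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(values)) {
    if (nm == "delta1") params$delta1 <- unname(values[[nm]])
    else if (nm %in% names(params$ku)) params$ku[[nm]] <- unname(values[[nm]])
    else params$pf[[nm]] <- unname(values[[nm]])
  }
  params
}

#' Effective ligand dissociation constants by binding context
#'
#' Kd values (nM) implied by the assembled parameter set for EGF and HRG in
#' their monomer and dimer contexts at the cell surface.  Context effects
#' are carried by the off-rate, so the printed ratios are exact:
#' `kd_egf_r12 = kd_egf_monomer / 1.6`, `kd_hrg_r23 = kd_hrg_monomer / 25`,
#' `kd_egf_r13h = kd_egf_monomer * 3`.
#'
#' @param params A `her_parameters` object.
#' @return Named numeric vector of Kd values.
#' @export
her_kd_table <- function(params) {
  stopifnot(inherits(params, "her_parameters"))
  b <- params$binding
  af <- params$affinity_fold
  kd1 <- b$koff1s / b$kon1s
  kd3 <- b$koff3s / b$kon3s
  c(kd_egf_monomer = kd1,
    kd_egf_r12 = (b$koff1s / af[["r12_egf"]]) / b$kon1s,
    kd_egf_r13h = (b$koff1s * af[["r13_hrg_egf"]]) / b$kon1s,
    kd_hrg_monomer = kd3,
    kd_hrg_r23 = (b$koff3s / af[["r23_hrg"]]) / b$kon3s)
}

#' @export
print.her_parameters <- function(x, ...) {
  cat("HER activation model parameters\n")
  cat(sprintf("  free: %d (20 ku + 26 pf + delta1);  delta1 = %.4g\n",
              length(her_free_names()), x$delta1))
  cat(sprintf("  kc (s, e): %.3g, %.3g (molecules/cell)^-1 min^-1\n",
              x$kc[["s"]], x$kc[["e"]]))
  cat(sprintf("  EGF-HER1 surface Kd: %.3g nM;  HRG-HER3 surface Kd: %.3g nM\n",
              x$binding$koff1s / x$binding$kon1s,
              x$binding$koff3s / x$binding$kon3s))
  cat("  ku range:", sprintf("[%.3g, %.3g] min^-1", min(x$ku), max(x$ku)), "\n")
  cat("  pf range:", sprintf("[%.3g, %.3g]", min(x$pf), max(x$pf)), "\n")
  invisible(x)
}

#' Shipped ground-truth parameter set
#'
#' The parameter set used as ground truth by the synthetic-data generator
#' and as the default configuration.  Identical to `her_parameters()` with
#' all defaults.
#'
#' @return A `her_parameters` object.
#' @export
her_truth_parameters <- function() her_parameters()
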