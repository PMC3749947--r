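# Trafficking-rate derivation.
#
# Internalized species in the early endosome are recycled to the surface or
# sorted to the late endosome, where they are degraded.  For species i with
# endosomal exit rate kx_i, recycling fraction f_i and sorting parameter
# delta_i (ratio of late-endosome entry to exit rates):
#
#   kr_i = kx_i * f_i * (1 + delta_i)          (recycling, min^-1)
#   kl_i = kx_i * (1 - f_i) * (1 + delta_i)    (LE entry, min^-1)
#   kd_i = kx_i * (1 - f_i) * (1 + delta_i) / delta_i   (degradation, min^-1)
#
# Sorting happens before late-endosome incorporation and all LE contents
# degrade at a common rate, which ties every delta_i to the EGFR-monomer
# value delta_1 through
#
#   1 + 1/delta_i = kx_1 (1 - f_1)(1 + 1/delta_1) / (kx_i (1 - f_i)).

#' Derive per-species trafficking rates from kx, f and delta1
#'
#' Computes the recycling rate `kr`, late-endosome entry rate `kl`,
#' degradation rate `kd` and sorting parameter `delta` for each species
#' from its endosomal exit rate and recycling fraction, anchoring the
#' sorting chain at the EGFR monomer (`kx1`, `f1`, `delta1`).  The
#' identities `kl/kd = delta` and `kr/(kr + kl) = f` hold exactly.
#'
#' @param kx Numeric vector of endosomal exit rates (min^-1), > 0.
#' @param f Numeric vector of recycling fractions in `[0, 1)` (recycled
#'   species with `f = 1` would never reach the degradation branch and are
#'   rejected because the sorting chain divides by `1 - f`).
#' @param delta1 Sorting parameter of the reference species (> 0).
#' @param kx1,f1 Exit rate and recycling fraction of the reference species;
#'   default to the first elements of `kx` and `f`.
#' @return A data.frame with columns `kx`, `f`, `delta`, `kr`, `kl`, `kd`.
#' @export
#' @examples
#' her_trafficking_rates(kx = 0.09, f = 0.5, delta1 = 1)
#' # kr = kl = kd = 0.09
her_trafficking_rates <- function(kx, f, delta1, kx1 = kx[1], f1 = f[1]) {
  if (length(f) != length(kx)) stop("kx and f must have the same length")
  if (any(!is.finite(kx)) || any(kx <= 0))
    stop("all kx must be positive and finite")
  if (any(f < 0) || any(f >= 1))
    stop("all recycling fractions must lie in [0, 1)")
  if (!is.finite(delta1) || delta1 <= 0) stop("delta1 must be > 0")
  a <- kx1 * (1 - f1) * (1 + 1 / delta1)   # common LE degradation scale
  ratio <- a / (kx * (1 - f))              # = 1 + 1/delta_i
  if (any(ratio <= 1))
    stop("sorting chain yields nonpositive delta for some species; ",
         "kx*(1-f) must stay below the reference LE degradation scale")
  delta <- 1 / (ratio - 1)
  kr <- kx * f * (1 + delta)
  kl <- kx * (1 - f) * (1 + delta)
  kd <- kl / delta
  data.frame(kx = kx, f = f, delta = delta, kr = kr, kl = kl, kd = kd)
}

# Per-species trafficking table for the full 17-species network.
# Returns internalization (kint: kt for monomers, ke for dimers), kr, kl,
# kd for every species in canonical order.  Ligands are a special class:
# surface free ligand is extracellular (not internalized; clamped by the
# protocol) and early-endosome free ligand released by unbinding is sorted
# to the late endosome at the reference sorting-loss rate and degraded
# there; it is never recycled.
.species_trafficking <- function(params) {
  key <- paste(c(params$trafficking$her1, params$trafficking$her23,
                 params$delta1), collapse = "|")
  hit <- .cache$traffic_key
  if (!is.null(hit) && identical(hit, key)) return(.cache$traffic)
  sp <- .species_table()
  tr1 <- params$trafficking$her1
  tr23 <- params$trafficking$her23
  kx1 <- tr1[["kx"]]; f1 <- tr1[["f"]]
  kx <- ifelse(sp$traffic_class == "her1", tr1[["kx"]], tr23[["kx"]])
  f <- ifelse(sp$traffic_class == "her1", tr1[["f"]], tr23[["f"]])
  rec <- sp$traffic_class != "ligand"
  rates <- her_trafficking_rates(kx[rec], f[rec], params$delta1,
                                 kx1 = kx1, f1 = f1)
  out <- data.frame(name = sp$name, kint = 0, kr = 0, kl = 0, kd = 0,
                    delta = NA_real_, stringsAsFactors = FALSE)
  out$kr[rec] <- rates$kr
  out$kl[rec] <- rates$kl
  out$kd[rec] <- rates$kd
  out$delta[rec] <- rates$delta
  kint <- numeric(nrow(sp))
  mono <- sp$kind == "monomer"
  dim <- sp$kind == "dimer"
  kint[mono] <- ifelse(sp$traffic_class[mono] == "her1",
                       tr1[["kt"]], tr23[["kt"]])
  kint[dim] <- ifelse(sp$traffic_class[dim] == "her1",
                      tr1[["ke"]], tr23[["ke"]])
  out$kint <- kint
  # ligand loss from the EE: sorted out at the reference rate, degraded in
  # the LE; contributes to no observable
  lig <- sp$traffic_class == "ligand"
  out$kl[lig] <- kx1 * (1 - f1)
  out$kd[lig] <- kx1
  .cache$traffic_key <- key
  .cache$traffic <- out
  out
}
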