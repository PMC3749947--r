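# Dimer-level analyses: phosphorylation decomposition, expression-grid
# scans and cell-line panel predictions.

#' Decompose receptor phosphorylation into per-dimer contributions
#'
#' For each receptor the phosphorylation signal is a pf-weighted sum of
#' dimer abundances over the surface and early endosome.  This returns
#' each dimer's absolute signal (pf x abundance, summed over the two
#' reactive compartments) and its fractional contribution at a requested
#' time.  Fractions over contributing dimers sum to one whenever the
#' total is positive.
#'
#' @param sim A [her_simulate()] result.
#' @param time Evaluation time (must be one of the simulated sample
#'   times); default the last.
#' @param level `"species"` for ligand-occupancy-resolved dimers (R11E vs
#'   R11EE, ...) or `"pair"` to roll contributions up to receptor pairs
#'   (R11, R12, R13, R22, R23, R33).
#' @return A data.frame with columns `receptor` (`pR1`..`pR3`), `dimer`,
#'   `signal`, `fraction`, `time_min`.
#' @export
her_decompose <- function(sim, time = max(sim$times),
                          level = c("species", "pair")) {
  stopifnot(inherits(sim, "her_sim"))
  level <- match.arg(level)
  ti <- match(time, sim$times)
  if (is.na(ti))
    stop("time ", time, " is not among the simulated sample times",
         call. = FALSE)
  state <- sim$states[ti, ]
  pm <- her_pf_map()
  params <- sim$params
  out <- list()
  for (rec in c("R1", "R2", "R3")) {
    rows <- pm[pm$receptor == rec, ]
    sig <- vapply(seq_len(nrow(rows)), function(k) {
      if (is.na(rows$pf_s[k])) return(0)
      params$pf[[rows$pf_s[k]]] * state[[.state_index(rows$dimer[k], "s")]] +
        params$pf[[rows$pf_i[k]]] * state[[.state_index(rows$dimer[k], "e")]]
    }, numeric(1))
    dimer <- rows$dimer
    if (level == "pair") {
      pair <- paste0("R", vapply(dimer, function(d) {
        sp <- .species_table()
        i <- match(d, sp$name)
        paste0(rep(c("1", "2", "3"), c(sp$n1[i], sp$n2[i], sp$n3[i])),
               collapse = "")
      }, character(1)))
      sig <- tapply(sig, pair, sum)
      dimer <- names(sig)
      sig <- as.vector(sig)
    }
    total <- sum(sig)
    out[[rec]] <- data.frame(
      receptor = paste0("pR", substr(rec, 2, 2)),
      dimer = dimer, signal = sig,
      fraction = if (total > 0) sig / total else NA_real_,
      time_min = time, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan predictions over a HER1 x HER2 expression grid
#'
#' Equilibrates, stimulates and decomposes the model at every point of a
#' log-spaced HER1 x HER2 grid with HER3 fixed, reporting HER1-3
#' phosphorylation and the per-pair dimer fractions at the evaluation
#' time.  Defaults follow the standard evaluation point: saturating
#' co-stimulation (30 ng/ml EGF + 100 ng/ml HRG) read out at 60 min, with
#' HER3 fixed at 40,000 receptors/cell (the level HER3-expressing cell
#' lines cluster around).
#'
#' @param params A [her_parameters()] object.
#' @param her1_range,her2_range Axis ranges (molecules/cell).
#' @param n Grid points per axis (log-spaced).
#' @param her3 Fixed HER3 expression.
#' @param egf_ng_ml,hrg_ng_ml Stimulation doses.
#' @param time Evaluation time, min.
#' @return A data.frame of class `her_grid`: one row per grid point with
#'   `her1`, `her2`, `her3`, `pR1t`, `pR2t`, `pR3t` and fraction columns
#'   `frac_<receptor>_<pair>`.
#' @export
her_grid_scan <- function(params, her1_range = c(1e3, 1e6),
                          her2_range = c(1e3, 3e6), n = 20,
                          her3 = 4e4, egf_ng_ml = 30, hrg_ng_ml = 100,
                          time = 60) {
  her1_axis <- 10^seq(log10(her1_range[1]), log10(her1_range[2]),
                      length.out = n)
  her2_axis <- 10^seq(log10(her2_range[1]), log10(her2_range[2]),
                      length.out = n)
  grid <- expand.grid(her1 = her1_axis, her2 = her2_axis)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prof <- her_profile(sprintf("grid_%d", i), her1 = grid$her1[i],
                        her2 = grid$her2[i], her3 = her3)
    sim <- her_simulate(params, prof, egf_ng_ml = egf_ng_ml,
                        hrg_ng_ml = hrg_ng_ml, times = c(0, time))
    dec <- her_decompose(sim, time = time, level = "pair")
    obs <- sim$observables[2, ]
    fr <- stats::setNames(dec$fraction,
                          paste0("frac_", dec$receptor, "_", dec$dimer))
    rows[[i]] <- c(her1 = grid$her1[i], her2 = grid$her2[i], her3 = her3,
                   obs[c("pR1t", "pR2t", "pR3t")], fr)
  }
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("her_grid", "data.frame")
  attr(out, "protocol") <- list(egf_ng_ml = egf_ng_ml,
                                hrg_ng_ml = hrg_ng_ml, time = time)
  out
}

#' Predict activation for a panel of cell lines
#'
#' Runs the standard evaluation protocol for each profile of a panel and
#' tabulates HER1-3 phosphorylation plus per-pair dimer fractions.
#'
#' @param params A [her_parameters()] object.
#' @param profiles Data.frame with columns `name`, `her1`, `her2`, `her3`
#'   (e.g. [her_panel_fixture()]).  An empty panel yields an empty table.
#' @param egf_ng_ml,hrg_ng_ml,time Protocol, as in [her_grid_scan()].
#' @return A data.frame, one row per profile.
#' @export
her_panel_predict <- function(params, profiles = her_panel_fixture(),
                              egf_ng_ml = 30, hrg_ng_ml = 100, time = 60) {
  if (nrow(profiles) == 0L) {
    return(data.frame(name = character(0), her1 = numeric(0),
                      her2 = numeric(0), her3 = numeric(0),
                      pR1t = numeric(0), pR2t = numeric(0),
                      pR3t = numeric(0)))
  }
  rows <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    prof <- her_profile(profiles$name[i], her1 = profiles$her1[i],
                        her2 = profiles$her2[i], her3 = profiles$her3[i])
    sim <- her_simulate(params, prof, egf_ng_ml = egf_ng_ml,
                        hrg_ng_ml = hrg_ng_ml, times = c(0, time))
    dec <- her_decompose(sim, time = time, level = "pair")
    obs <- sim$observables[2, ]
    fr <- stats::setNames(dec$fraction,
                          paste0("frac_", dec$receptor, "_", dec$dimer))
    rows[[i]] <- data.frame(name = profiles$name[i], her1 = profiles$her1[i],
                            her2 = profiles$her2[i], her3 = profiles$her3[i],
                            t(c(obs[c("pR1t", "pR2t", "pR3t")], fr)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
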