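# Synthetic ELISA-like datasets.
#
# The generator emulates the study's measurement design: four cell lines,
# EGF dose series 0.6-30 ng/ml and HRG dose series 4-120 ng/ml sampled at
# 0/10/30/60 min (total phospho only), detailed 2-h time courses for
# 12 ng/ml EGF and/or 40 ng/ml HRG (total phospho, internal phospho and
# receptor mass), and 2C4-blocking conditions at 10 and 30 min.  Noise is
# multiplicative lognormal with a configurable CV per measurement.

.measurement_labels <- c("pR1t", "pR2t", "pR3t", "pR1i", "pR2i", "pR3i",
                         "mR1t", "mR2t", "mR3t")

#' The default study-emulating measurement design
#'
#' One row per (cell line, treatment, time, measurement).  Dose grids are
#' frozen at EGF {0.6, 3, 12, 30} ng/ml and HRG {4, 12, 40, 120} ng/ml
#' (the study prints the ranges; the intermediate doses are package
#' choices), sampled at {0, 10, 30, 60} min for total phospho.  Time
#' courses at 12 ng/ml EGF and/or 40 ng/ml HRG cover 0-120 min for all
#' nine measurement types, and 95% HER2-blocking conditions are measured
#' at 10 and 30 min.
#'
#' @param cell_lines Character vector of fixture line names.
#' @param replicates Replicate count per measurement (>= 2).
#' @return A data.frame of class `her_design` with columns `cell_line`,
#'   `egf_ng_ml`, `hrg_ng_ml`, `block`, `time_min`, `measurement`,
#'   `replicates`.
#' @export
her_design_default <- function(cell_lines = her_cell_lines()$name,
                               replicates = 2L) {
  if (replicates < 2L) stop("the design requires replicates >= 2")
  pr <- c("pR1t", "pR2t", "pR3t")
  rows <- list()
  grid <- function(cl, egf, hrg, block, tt, meas) {
    expand.grid(cell_line = cl, egf_ng_ml = egf, hrg_ng_ml = hrg,
                block = block, time_min = tt, measurement = meas,
                stringsAsFactors = FALSE)
  }
  for (cl in cell_lines) {
    for (d in c(0.6, 3, 12, 30))
      rows[[length(rows) + 1L]] <- grid(cl, d, 0, 0, c(0, 10, 30, 60), pr)
    for (d in c(4, 12, 40, 120))
      rows[[length(rows) + 1L]] <- grid(cl, 0, d, 0, c(0, 10, 30, 60), pr)
    tc <- c(0, 5, 10, 20, 30, 45, 60, 90, 120)
    rows[[length(rows) + 1L]] <- grid(cl, 12, 0, 0, tc, .measurement_labels)
    rows[[length(rows) + 1L]] <- grid(cl, 0, 40, 0, tc, .measurement_labels)
    rows[[length(rows) + 1L]] <- grid(cl, 12, 40, 0, tc, .measurement_labels)
    rows[[length(rows) + 1L]] <- grid(cl, 12, 0, 0.95, c(10, 30), pr)
    rows[[length(rows) + 1L]] <- grid(cl, 0, 40, 0.95, c(10, 30), pr)
  }
  design <- do.call(rbind, rows)
  design$replicates <- as.integer(replicates)
  class(design) <- c("her_design", "data.frame")
  design
}

#' A reduced desk-scale measurement design
#'
#' A thinned version of [her_design_default()] used where many model
#' evaluations per dataset are needed (multistart fitting, tests): two
#' doses per ligand, coarser time courses, no blocking conditions.  The
#' three time-course treatments (EGF alone, HRG alone, combined) are all
#' retained because the single-ligand courses carry the information that
#' separates the EGF-driven, HRG-driven and mixed dimer blocks.
#'
#' @inheritParams her_design_default
#' @return A `her_design` data.frame.
#' @export
her_design_small <- function(cell_lines = her_cell_lines()$name,
                             replicates = 2L) {
  pr <- c("pR1t", "pR2t", "pR3t")
  rows <- list()
  grid <- function(cl, egf, hrg, tt, meas) {
    expand.grid(cell_line = cl, egf_ng_ml = egf, hrg_ng_ml = hrg,
                block = 0, time_min = tt, measurement = meas,
                stringsAsFactors = FALSE)
  }
  tc <- c(0, 10, 30, 60, 120)
  for (cl in cell_lines) {
    for (d in c(3, 30))
      rows[[length(rows) + 1L]] <- grid(cl, d, 0, c(0, 10, 30, 60), pr)
    for (d in c(12, 120))
      rows[[length(rows) + 1L]] <- grid(cl, 0, d, c(0, 10, 30, 60), pr)
    rows[[length(rows) + 1L]] <- grid(cl, 12, 0, tc, .measurement_labels)
    rows[[length(rows) + 1L]] <- grid(cl, 0, 40, tc, .measurement_labels)
    rows[[length(rows) + 1L]] <- grid(cl, 12, 40, tc, .measurement_labels)
  }
  design <- do.call(rbind, rows)
  design$replicates <- as.integer(replicates)
  class(design) <- c("her_design", "data.frame")
  design
}

#' Generate a synthetic ELISA dataset from known ground truth
#'
#' Simulates every condition of a measurement design under a ground-truth
#' parameter set and applies multiplicative lognormal noise with the given
#' coefficient of variation.  `cv = 0` reproduces the noiseless model
#' output exactly, and the result is byte-identical for a fixed seed.
#'
#' @param design A `her_design` data.frame (see [her_design_default()]).
#' @param truth A [her_parameters()] object: the generating parameters.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.1, typical ELISA replicate scatter).
#' @param seed Integer RNG seed.
#' @param profiles Cell-line expression table (default the study
#'   fixtures).
#' @param floor Detection floor: values are censored from below at this
#'   level after noising (default 0, no censoring).
#' @return A data.frame of class `her_dataset` with columns `cell_line`,
#'   `egf_ng_ml`, `hrg_ng_ml`, `block`, `time_min`, `measurement`,
#'   `replicate`, `value` and attributes `seed`, `cv`.
#' @export
her_synthesize <- function(design, truth = her_truth_parameters(),
                           cv = 0.1, seed = 1L,
                           profiles = her_cell_lines(), floor = 0) {
  stopifnot(inherits(truth, "her_parameters"))
  if (cv < 0) stop("cv must be >= 0")
  preds <- her_predict_design(design, truth, profiles)
  reps <- design$replicates
  n <- nrow(design)
  out <- design[rep(seq_len(n), times = reps),
                c("cell_line", "egf_ng_ml", "hrg_ng_ml", "block",
                  "time_min", "measurement")]
  out$replicate <- unlist(lapply(reps, seq_len))
  mu <- rep(preds, times = reps)
  set.seed(seed)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    # mean-one multiplicative noise
    fac <- exp(rnorm(length(mu), mean = -sdlog^2 / 2, sd = sdlog))
    out$value <- pmax(mu * fac, floor)
  } else {
    out$value <- pmax(mu, floor)
  }
  rownames(out) <- NULL
  structure(out, class = c("her_dataset", "data.frame"),
            seed = seed, cv = cv)
}

#' Model predictions for every record of a design
#'
#' Simulates each unique (cell line, EGF, HRG, block) condition once at
#' the union of its sample times and returns the noiseless prediction for
#' each design record, in design order.
#'
#' @inheritParams her_synthesize
#' @param params Parameter set to predict with.
#' @param rtol,atol Integrator tolerances.
#' @return Numeric vector, `nrow(design)` long.
#' @export
her_predict_design <- function(design, params, profiles = her_cell_lines(),
                               rtol = 1e-8, atol = 1e-10) {
  need <- c("cell_line", "egf_ng_ml", "hrg_ng_ml", "block", "time_min",
            "measurement")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(design$measurement, .measurement_labels)
  if (length(bad) > 0)
    stop("unknown measurement label(s): ", paste(bad, collapse = ", "))
  key <- paste(design$cell_line, design$egf_ng_ml, design$hrg_ng_ml,
               design$block)
  preds <- numeric(nrow(design))
  eq_cache <- new.env(parent = emptyenv())
  for (k in unique(key)) {
    idx <- which(key == k)
    cl <- design$cell_line[idx[1L]]
    prow <- profiles[match(cl, profiles$name), ]
    if (any(is.na(prow)))
      stop("no expression profile for cell line '", cl, "'")
    profile <- her_profile(cl, her1 = prow$her1, her2 = prow$her2,
                           her3 = prow$her3)
    block <- design$block[idx[1L]]
    eq_key <- paste(cl, block)
    if (is.null(eq_cache[[eq_key]])) {
      eq_cache[[eq_key]] <-
        her_equilibrate(her_apply_block(profile, block)$available, params)
    }
    tt <- sort(unique(design$time_min[idx]))
    sim <- tryCatch(
      her_simulate(params, profile,
                   egf_ng_ml = design$egf_ng_ml[idx[1L]],
                   hrg_ng_ml = design$hrg_ng_ml[idx[1L]],
                   times = tt, block_fraction = block,
                   equilibrium = eq_cache[[eq_key]],
                   rtol = rtol, atol = atol),
      error = function(e)
        stop("simulation failed for condition [", k, "]: ",
             conditionMessage(e), call. = FALSE))
    ti <- match(design$time_min[idx], sim$times)
    mi <- match(design$measurement[idx], colnames(sim$observables))
    preds[idx] <- sim$observables[cbind(ti, mi)]
  }
  preds
}
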