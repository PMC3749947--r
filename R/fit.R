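# Parameter estimation: scaled residuals, bound-constrained nonlinear
# least squares, progressive multistart, and solution clustering.
#
# The 47 free parameters are estimated by fitting model predictions to a
# measurement dataset.  Residuals are scaled by the maximum observed value
# of each measurement type so phospho and mass measurements contribute
# comparably; rate and pf parameters are optimized in log10 space (their
# prior ranges span 3-6 decades), the sorting parameter delta1 in linear
# space.  A progressive strategy fits HER1-related parameters on the
# parental line first, extends to the HER1-HER2 and HER1-HER3 pairs, and
# finally estimates all parameters on all lines with randomized initial
# guesses for the HER2-HER3 interaction.

# free-parameter search space: sampling ranges double as box constraints
.free_bounds <- function() {
  nm <- her_free_names()
  data.frame(
    name = nm,
    transform = ifelse(nm == "delta1", "linear", "log10"),
    lower = ifelse(nm == "delta1", 0.1,
                   ifelse(grepl("^ku", nm), 1e-3, 1e-6)),
    upper = ifelse(nm == "delta1", 10,
                   ifelse(grepl("^ku", nm), 1e3, 1)),
    stringsAsFactors = FALSE
  )
}

.encode_free <- function(values) {
  b <- .free_bounds()
  b <- b[match(names(values), b$name), ]
  stats::setNames(ifelse(b$transform == "log10", log10(values), values),
                  names(values))
}

.decode_free <- function(theta, names) {
  b <- .free_bounds()
  b <- b[match(names, b$name), ]
  stats::setNames(ifelse(b$transform == "log10", 10^theta, theta), names)
}

.encoded_bounds <- function(names) {
  b <- .free_bounds()
  b <- b[match(names, b$name), ]
  lower <- ifelse(b$transform == "log10", log10(b$lower), b$lower)
  upper <- ifelse(b$transform == "log10", log10(b$upper), b$upper)
  list(lower = lower, upper = upper)
}

# parameter groups used by the progressive strategy
.param_groups <- function() {
  g <- list(
    her1 = c("ku11es", "ku11ees", "ku11ei", "ku11eei",
             "pf11es", "pf11ees", "pf11ei", "pf11eei", "delta1"),
    r12 = c("ku12es", "ku12ei", "ku22s", "ku22i",
            "pf12es", "pf12ei", "pf21es", "pf21ei", "pf22s", "pf22i"),
    r13 = c("ku13es", "ku13ei", "ku13hs", "ku13hi", "ku13ehs", "ku13ehi",
            "ku33hs", "ku33hi", "ku33hhs", "ku33hhi",
            "pf13es", "pf13ei", "pf13hs", "pf13hi", "pf13ehs", "pf13ehi",
            "pf31es", "pf31ei", "pf31hs", "pf31hi", "pf31ehs", "pf31ehi"),
    r23 = c("ku23hs", "ku23hi", "pf23hs", "pf23hi", "pf32hs", "pf32hi")
  )
  stopifnot(identical(sort(unlist(g, use.names = FALSE)),
                      sort(her_free_names())))
  g
}

#' Residual scaling constants of a dataset
#'
#' The maximum observed value per measurement type, used to scale
#' residuals so distinct measurement types contribute comparably to the
#' objective.
#'
#' @param data A `her_dataset` (or any data.frame with `measurement` and
#'   `value` columns).
#' @return Named numeric vector of scales (zero maxima are replaced by 1).
#' @export
her_scales <- function(data) {
  s <- tapply(data$value, data$measurement, max)
  s[!is.finite(s) | s <= 0] <- 1
  s <- s[.measurement_labels[.measurement_labels %in% names(s)]]
  unlist(as.list(s))
}

#' Assemble the scaled residual vector
#'
#' `residual_k = (prediction_k - value_k) / scale(type_k)`, concatenated
#' over all records.  Doubling every measurement and every prediction
#' leaves the residuals unchanged (the scales double too when recomputed
#' from the doubled data).
#'
#' @param data Dataset records with `measurement` and `value`.
#' @param predictions Numeric vector of model predictions, one per record.
#' @param scales Named scale vector from [her_scales()]; recomputed from
#'   `data` when omitted.
#' @return Numeric residual vector with attribute `"rmse"`.
#' @export
her_residuals_scaled <- function(data, predictions, scales = her_scales(data)) {
  if (length(predictions) != nrow(data))
    stop("need one prediction per record (got ", length(predictions),
         " for ", nrow(data), " records)", call. = FALSE)
  if (anyNA(predictions))
    stop("missing prediction for at least one record", call. = FALSE)
  sc <- scales[data$measurement]
  if (anyNA(sc))
    stop("no scale for measurement type(s): ",
         paste(unique(data$measurement[is.na(sc)]), collapse = ", "),
         call. = FALSE)
  r <- (predictions - data$value) / sc
  attr(r, "rmse") <- sqrt(mean(r^2))
  r
}

#' Root-mean-squared error of scaled residuals
#' @param residuals Output of [her_residuals_scaled()].
#' @return A single number.
#' @export
her_rmse <- function(residuals) sqrt(mean(residuals^2))

# residual closure for the optimizer: simulation failures are penalized
# with a large finite residual (10x the typical scaled-residual ceiling),
# never raised
.make_objective <- function(data, params, free_names, profiles, scales,
                            rtol, atol, penalty = 10) {
  force(list(data, params, free_names, profiles, scales, rtol, atol))
  function(theta) {
    pars <- her_set_free(params, .decode_free(theta, free_names))
    pred <- tryCatch(
      her_predict_design(data, pars, profiles, rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(pred) || anyNA(pred) || any(!is.finite(pred)))
      return(rep(penalty, nrow(data)))
    as.vector(her_residuals_scaled(data, pred, scales))
  }
}

#' Fit free parameters from a single start
#'
#' Bound-constrained Levenberg-Marquardt minimization of the scaled
#' residual vector over a chosen subset of the free parameters, in
#' transformed (log10/linear) space.
#'
#' @param data A `her_dataset`.
#' @param params Template [her_parameters()] object supplying all
#'   parameters not being fitted.
#' @param start Named numeric vector of starting values (natural scale)
#'   for the parameters to fit; its names define the free subset.
#' @param profiles Expression table for the cell lines in `data`.
#' @param scales Residual scales; recomputed from `data` when omitted.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @param rtol,atol Integrator tolerances used during fitting.
#' @return A list: `par` (fitted values, natural scale), `rmse`,
#'   `converged`, `niter`, `message`, `start`.
#' @export
her_fit_single <- function(data, params, start,
                           profiles = her_cell_lines(),
                           scales = her_scales(data),
                           maxiter = 25L, rtol = 1e-7, atol = 1e-9) {
  free_names <- names(start)
  bad <- setdiff(free_names, her_free_names())
  if (length(bad) > 0)
    stop("not free parameters: ", paste(bad, collapse = ", "))
  bb <- .encoded_bounds(free_names)
  theta0 <- pmin(pmax(.encode_free(start), bb$lower), bb$upper)
  fn <- .make_objective(data, params, free_names, profiles, scales,
                        rtol, atol)
  # epsfcn keeps the finite-difference step well above integrator noise;
  # with log10-transformed parameters the step is ~1e-4 decades
  res <- minpack.lm::nls.lm(
    par = theta0, lower = bb$lower, upper = bb$upper, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-13,
                                         ptol = 1e-11, gtol = 0,
                                         epsfcn = 1e-8))
  r <- fn(res$par)
  # info 1-4: an LM convergence test fired; -1: iteration cap reached with
  # a usable terminal point.  Only numerical failure counts as unconverged.
  list(par = .decode_free(res$par, free_names),
       rmse = her_rmse(r),
       converged = res$info %in% c(1:4, -1L) && all(is.finite(res$par)),
       info = res$info,
       niter = res$niter,
       message = res$message,
       start = start)
}

# draw uniform starts in transformed space for a set of parameters
.draw_starts <- function(free_names, n) {
  bb <- .encoded_bounds(free_names)
  out <- matrix(runif(n * length(free_names), min = rep(bb$lower, each = n),
                      max = rep(bb$upper, each = n)),
                nrow = n, dimnames = list(NULL, free_names))
  out
}

#' Progressive multistart parameter estimation
#'
#' Fits the 47 free parameters of the HER activation model to a dataset
#' using a progressive strategy.  Stage 1 estimates the HER1-related
#' parameters (R11 dissociation rates, R11 pf values, delta1) on the
#' parental line's HER1 observables, by Levenberg-Marquardt from
#' objective-screened random multistarts with the leading candidates
#' polished.  Stage 2 extends to the HER1-HER2 block (R12/R22; parental
#' plus HER2+3- lines, HER1/HER2 observables) and the HER1-HER3 block
#' (R13/R33; parental plus HER2-3+ lines, HER1/HER3 observables), each
#' explored as a block and then polished jointly with the HER1 block.  A
#' refinement pass then re-explores the HER1 block from scratch — its
#' stage-1 optimum is biased by trace couplings through the then-unknown
#' cross blocks — and refits the stage-2 blocks.  Stage 3 draws
#' `n_starts` random HER2-HER3 (R23) guesses, fits each on the
#' co-expressing line(s) and continues on all lines; the best start
#' seeds a final joint fit of all 47 parameters on the full dataset.
#' Converged stage-3 solutions within an RMSE margin of the best are
#' clustered by k-means on standardized log-parameters and summarized by
#' per-cluster minimum-RMSE representatives.
#'
#' All free parameters of the template are reset to the geometric middle
#' of their bounds before stage 1, so the outcome does not depend on the
#' template's (possibly informative) free values.
#'
#' @param data A `her_dataset` covering the four study cell lines.
#' @param params Template parameter set (fixed parameters are taken from
#'   it; free parameters are reset).
#' @param profiles Expression table for the cell lines in `data`.
#' @param n_starts Number of stage-3 multistart runs (the study used 500;
#'   desk-scale analyses use 10-20).
#' @param seed Master RNG seed; all stage randomness derives from it.
#' @param rmse_margin Retention margin for clustering: solutions with
#'   RMSE <= margin x best are retained (default 1.2).
#' @param k_range Candidate cluster counts for the silhouette criterion.
#' @param control List of knobs overriding the staged iteration caps and
#'   screening sizes (`stage1_starts`, `stage2_starts`, `screen1`,
#'   `screen2`, `maxiter_stage1`, `maxiter`, `maxiter_polish`,
#'   `polish_top`, `maxiter_stage2_polish`, `maxiter_r23`,
#'   `maxiter_r23_full`, `maxiter_final`, `rtol`, `atol`).
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `her_fit`; see [summary.her_fit()].
#' @export
her_fit <- function(data, params = her_parameters(),
                    profiles = her_cell_lines(),
                    n_starts = 20L, seed = 1L,
                    rmse_margin = 1.2, k_range = 2:10,
                    control = list(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ctl <- utils::modifyList(list(
    stage1_starts = max(8L, n_starts %/% 3L),
    stage2_starts = 2L,
    screen1 = 120L,        # cheap objective screens before stage-1 LM
    screen2 = 40L,         # screens for the stage-2 extension blocks
    maxiter_stage1 = 60L,  # exploration on the parental line
    maxiter = 40L,         # stage-2 exploration
    maxiter_polish = 120L, # refinement of the top stage-1 candidates
    polish_top = 3L,       # how many stage-1 candidates to polish
    maxiter_stage2_polish = 60L,
    maxiter_r23 = 20L,     # stage 3: R23 exploration on the co-expressor
    maxiter_cycle = 20L,   # final phase: per-block refits on all lines
    maxiter_final = 40L,   # final joint all-47 fit from the incumbent
    rtol = 1e-7, atol = 1e-9
  ), control)
  t_start <- Sys.time()
  set.seed(seed)
  groups <- .param_groups()
  # neutral template: free parameters at the geometric middle of bounds
  b <- .free_bounds()
  mid <- stats::setNames(
    ifelse(b$transform == "log10", 10^((log10(b$lower) + log10(b$upper)) / 2),
           (b$lower + b$upper) / 2), b$name)
  params <- her_set_free(params, mid)

  lines_of <- function(x) unique(x$cell_line)
  # each stage sees only the measurements its parameters inform, so the
  # trace expression of the other receptors cannot bias the stage optimum
  pick <- function(lns, meas = NULL) {
    miss <- setdiff(lns, lines_of(data))
    if (length(miss) > 0)
      stop("dataset lacks cell line(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    d <- data[data$cell_line %in% lns, , drop = FALSE]
    if (!is.null(meas)) d <- d[d$measurement %in% meas, , drop = FALSE]
    d
  }
  meas_of <- function(recs) {
    as.vector(outer(recs, c("t", "i"), function(r, s)
      paste0("pR", r, s))) |>
      c(paste0("mR", recs, "t"))
  }
  scales <- her_scales(data)

  run_stage <- function(stage_data, starts, maxiter, polish = 0L,
                        polish_top = 1L, tmpl = params) {
    sols <- vector("list", nrow(starts))
    for (i in seq_len(nrow(starts))) {
      sols[[i]] <- her_fit_single(
        stage_data, tmpl, .decode_free(starts[i, ], colnames(starts)),
        profiles = profiles, scales = scales,
        maxiter = maxiter, rtol = ctl$rtol, atol = ctl$atol)
    }
    ok <- vapply(sols, function(s) s$converged, logical(1))
    if (!any(ok))
      stop("estimation stage had zero converged runs; best residual RMSE ",
           signif(min(vapply(sols, `[[`, numeric(1), "rmse")), 3),
           call. = FALSE)
    rm <- vapply(sols, function(s) ifelse(s$converged, s$rmse, Inf),
                 numeric(1))
    best <- sols[[which.min(rm)]]
    if (polish > 0L) {
      # polish the leading candidates: the eventual global basin need not
      # hold the lowest RMSE after capped exploration
      for (i in utils::head(order(rm), polish_top)) {
        if (!is.finite(rm[i])) next
        pb <- her_fit_single(stage_data, tmpl, sols[[i]]$par,
                             profiles = profiles, scales = scales,
                             maxiter = polish, rtol = ctl$rtol,
                             atol = ctl$atol)
        if (pb$converged && pb$rmse < best$rmse) best <- pb
      }
    }
    list(all = sols, best = best)
  }

  # objective-screened multistart: draw many candidates, evaluate the
  # objective once each, and hand only the most promising to LM — far
  # better basin coverage per unit time than fitting every draw
  screen_starts <- function(stage_data, cand, top_n, tmpl = params) {
    fnobj <- .make_objective(stage_data, tmpl, colnames(cand), profiles,
                             scales, ctl$rtol, ctl$atol)
    r0 <- apply(cand, 1, function(th) her_rmse(fnobj(th)))
    cand[utils::head(order(r0), top_n), , drop = FALSE]
  }

  # a stage that explores one new parameter block by screened multistart
  # (everything else frozen at the current estimate), then polishes the
  # block jointly with the HER1 block
  block_stage <- function(stage_data, block, cur, n_starts2) {
    tmpl <- her_set_free(params, cur)
    cand <- screen_starts(
      stage_data, .draw_starts(block, max(ctl$screen2, n_starts2)),
      n_starts2, tmpl)
    st <- run_stage(stage_data, cand, ctl$maxiter, tmpl = tmpl)
    cur[block] <- st$best$par[block]
    joint <- c(groups$her1, block)
    pb <- her_fit_single(stage_data, her_set_free(params, cur), cur[joint],
                         profiles = profiles, scales = scales,
                         maxiter = ctl$maxiter_stage2_polish,
                         rtol = ctl$rtol, atol = ctl$atol)
    if (pb$converged && pb$rmse <= st$best$rmse) cur[joint] <- pb$par
    list(cur = cur, rmse = min(st$best$rmse, pb$rmse))
  }

  # stage 1: HER1 parameters on the parental line
  d1 <- pick("parental", meas_of(1))
  st1_starts <- screen_starts(
    d1, .draw_starts(groups$her1, max(ctl$screen1, ctl$stage1_starts)),
    ctl$stage1_starts)
  t1 <- Sys.time()
  st1 <- run_stage(d1, st1_starts, ctl$maxiter_stage1,
                   ctl$maxiter_polish, ctl$polish_top)
  say("stage 1 (HER1): best RMSE %.3g [%.1f min]", st1$best$rmse,
      as.numeric(difftime(Sys.time(), t1, units = "mins")))
  cur <- her_free_values(params)
  cur[groups$her1] <- st1$best$par[groups$her1]

  # stage 2a: + HER1-HER2 (R12, R22) on parental + HER2+3-
  d2a <- pick(c("parental", "24H"), meas_of(c(1, 2)))
  t2 <- Sys.time()
  s2a <- block_stage(d2a, groups$r12, cur, ctl$stage2_starts)
  cur <- s2a$cur
  say("stage 2a (R12/R22): best RMSE %.3g [%.1f min]", s2a$rmse,
      as.numeric(difftime(Sys.time(), t2, units = "mins")))

  # stage 2b: + HER1-HER3 (R13, R33) on parental + HER2-3+
  d2b <- pick(c("parental", "B5"), meas_of(c(1, 3)))
  t2b <- Sys.time()
  s2b <- block_stage(d2b, groups$r13, cur, ctl$stage2_starts)
  cur <- s2b$cur
  say("stage 2b (R13/R33): best RMSE %.3g [%.1f min]", s2b$rmse,
      as.numeric(difftime(Sys.time(), t2b, units = "mins")))

  # refinement pass: with the cross blocks estimated, the HER1 block is
  # re-explored from scratch (its stage-1 optimum was biased by the trace
  # couplings through the then-unknown R12/R13 parameters), and the
  # stage-2 blocks are refit from the updated values
  tr1 <- Sys.time()
  tmplr <- her_set_free(params, cur)
  st1r_starts <- screen_starts(
    d1, .draw_starts(groups$her1, max(ctl$screen1, ctl$polish_top)),
    ctl$polish_top, tmplr)
  st1r <- run_stage(d1, st1r_starts, ctl$maxiter_stage1,
                    ctl$maxiter_polish, 1L, tmplr)
  if (st1r$best$rmse < Inf) cur[groups$her1] <- st1r$best$par[groups$her1]
  for (blk in list(list(d2a, groups$r12), list(d2b, groups$r13))) {
    joint <- c(groups$her1, blk[[2]])
    rb <- her_fit_single(blk[[1]], her_set_free(params, cur), cur[joint],
                         profiles = profiles, scales = scales,
                         maxiter = ctl$maxiter, rtol = ctl$rtol,
                         atol = ctl$atol)
    if (rb$converged) cur[joint] <- rb$par
  }
  say("refinement pass: HER1 re-fit RMSE %.3g [%.1f min]", st1r$best$rmse,
      as.numeric(difftime(Sys.time(), tr1, units = "mins")))

  # stage 3: each start fits its randomized HER2-HER3 (R23) block with
  # everything else held at the refined solution, on the data of the
  # HER2/HER3 co-expressing line(s) where that block carries the most
  # signal; each terminal point is then scored on the full dataset
  all_names <- her_free_names()
  base_par <- cur
  co <- profiles$name[profiles$her2 >= 1e4 & profiles$her3 >= 1e4]
  d23 <- if (length(co) > 0) data[data$cell_line %in% co, , drop = FALSE]
         else data
  tmpl3 <- her_set_free(params, base_par)
  fn_full <- .make_objective(data, params, all_names, profiles, scales,
                             ctl$rtol, ctl$atol)
  st3_r23 <- .draw_starts(groups$r23, n_starts)
  sols3 <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    pre <- her_fit_single(
      d23, tmpl3, .decode_free(st3_r23[i, ], groups$r23),
      profiles = profiles, scales = scales,
      maxiter = ctl$maxiter_r23, rtol = ctl$rtol, atol = ctl$atol)
    full_par <- base_par
    full_par[groups$r23] <- pre$par
    sols3[[i]] <- list(par = full_par,
                       rmse = her_rmse(fn_full(.encode_free(full_par))),
                       converged = pre$converged, info = pre$info,
                       niter = pre$niter, message = pre$message,
                       start = .decode_free(st3_r23[i, ], groups$r23))
    say("stage 3 start %d/%d: full-data RMSE %.3g", i, n_starts,
        sols3[[i]]$rmse)
  }
  conv <- vapply(sols3, function(s) s$converged, logical(1))
  if (!any(conv))
    stop("stage 3 had zero converged runs", call. = FALSE)

  # final estimation from the incumbent: one block-coordinate cycle
  # (HER1, R12, R13, R23 in turn, each on the full dataset) straightens
  # the solution without letting a joint step trade one block against
  # another along the ku-pf degeneracy, then all 47 parameters are fit
  # jointly
  ib <- which(conv)[which.min(vapply(sols3[conv], `[[`, numeric(1), "rmse"))]
  fin <- sols3[[ib]]$par
  for (blk in list(groups$her1, groups$r12, groups$r13, groups$r23)) {
    fb <- her_fit_single(data, her_set_free(params, fin), fin[blk],
                         profiles = profiles, scales = scales,
                         maxiter = ctl$maxiter_cycle,
                         rtol = ctl$rtol, atol = ctl$atol)
    if (fb$converged) fin[blk] <- fb$par
  }
  pol <- her_fit_single(data, params, fin,
                        profiles = profiles, scales = scales,
                        maxiter = ctl$maxiter_final,
                        rtol = ctl$rtol, atol = ctl$atol)
  if (pol$converged && pol$rmse < sols3[[ib]]$rmse) sols3[[ib]] <- pol
  say("final all-parameter fit: RMSE %.3g", sols3[[ib]]$rmse)

  par_mat <- do.call(rbind, lapply(sols3, function(s) s$par))
  solutions <- data.frame(
    start = seq_len(n_starts),
    converged = conv,
    rmse = vapply(sols3, `[[`, numeric(1), "rmse")
  )
  solutions <- cbind(solutions, as.data.frame(par_mat))
  clust <- her_cluster_solutions(par_mat[conv, , drop = FALSE],
                                 solutions$rmse[conv],
                                 rmse_margin = rmse_margin,
                                 k_range = k_range)
  best_idx <- which(conv)[which.min(solutions$rmse[conv])]

  structure(list(
    solutions = solutions,
    best = sols3[[best_idx]]$par,
    best_rmse = solutions$rmse[best_idx],
    clusters = clust,
    conv_index = which(conv),
    stages = list(stage1_rmse = st1$best$rmse, stage2_r12_rmse = s2a$rmse,
                  stage2_r13_rmse = s2b$rmse,
                  refine_rmse = st1r$best$rmse, refined = cur),
    data = data, profiles = profiles,
    params_template = params, scales = scales,
    n_starts = n_starts, seed = seed,
    rmse_margin = rmse_margin,
    elapsed_min = as.numeric(difftime(Sys.time(), t_start, units = "mins"))
  ), class = "her_fit")
}

# mean silhouette width for a clustering (hand-rolled on a distance matrix)
.mean_silhouette <- function(X, labels) {
  d <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster converged solutions and pick representatives
#'
#' Retains solutions with RMSE within `rmse_margin` of the best, runs
#' k-means on standardized transformed parameters (log10 for rates and pf,
#' linear for delta1), chooses k by maximal mean silhouette width over
#' `k_range`, and returns the minimum-RMSE member of each cluster as its
#' representative.  Degenerate inputs (fewer than two retained or all
#' identical) collapse to a single cluster.
#'
#' @param par_mat Numeric matrix of solutions (rows) by free parameters
#'   (columns, natural scale, named).
#' @param rmse RMSE per solution.
#' @param rmse_margin Retention threshold: keep `rmse <= margin * min`.
#' @param k_range Candidate k values (restricted to `2:(n_retained - 1)`).
#' @return A list: `retained` (row indices into `par_mat`), `labels`
#'   (cluster per retained solution), `k`, `silhouette`,
#'   `representatives` (row indices into `par_mat`, one per cluster).
#' @export
her_cluster_solutions <- function(par_mat, rmse, rmse_margin = 1.2,
                                  k_range = 2:10) {
  stopifnot(nrow(par_mat) == length(rmse))
  keep <- which(rmse <= rmse_margin * min(rmse))
  one_cluster <- function() {
    list(retained = keep, labels = rep(1L, length(keep)), k = 1L,
         silhouette = NA_real_,
         representatives = keep[which.min(rmse[keep])])
  }
  if (length(keep) < 3L) return(one_cluster())
  X <- par_mat[keep, , drop = FALSE]
  b <- .free_bounds()
  for (j in seq_len(ncol(X))) {
    if (b$transform[match(colnames(X)[j], b$name)] == "log10")
      X[, j] <- log10(X[, j])
  }
  sds <- apply(X, 2, sd)
  X <- X[, sds > 1e-12, drop = FALSE]
  if (ncol(X) == 0L) return(one_cluster())
  X <- scale(X)
  ks <- k_range[k_range >= 2 & k_range <= length(keep) - 1L]
  if (length(ks) == 0L) return(one_cluster())
  best <- NULL
  for (k in ks) {
    km <- kmeans(X, centers = k, nstart = 10, iter.max = 50)
    sil <- .mean_silhouette(X, km$cluster)
    if (is.null(best) || sil > best$sil)
      best <- list(k = k, sil = sil, labels = km$cluster)
  }
  reps <- vapply(seq_len(best$k), function(g) {
    members <- keep[best$labels == g]
    members[which.min(rmse[members])]
  }, numeric(1))
  list(retained = keep, labels = best$labels, k = best$k,
       silhouette = best$sil, representatives = as.integer(reps))
}
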