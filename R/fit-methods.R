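# S3 methods for fitted model objects.

#' @export
print.her_fit <- function(x, ...) {
  n_conv <- length(x$conv_index)
  cat("Progressive multistart fit of the HER activation model\n")
  cat(sprintf("  %d stage-3 starts, %d converged;  best scaled RMSE %.4g\n",
              x$n_starts, n_conv, x$best_rmse))
  cat(sprintf("  %d solutions within %.2gx of the best RMSE, %d cluster(s)\n",
              length(x$clusters$retained), x$rmse_margin, x$clusters$k))
  cat(sprintf("  fitted in %.1f min (seed %d)\n", x$elapsed_min, x$seed))
  invisible(x)
}

#' Summarize a fitted HER model
#'
#' @param object A `her_fit` object.
#' @param ... Unused.
#' @return A list of class `summary.her_fit` with the solution table,
#'   cluster sizes, representative parameter sets and the spread (log10
#'   range) of each parameter across retained solutions — wide ranges
#'   flag weakly identifiable parameters.
#' @export
summary.her_fit <- function(object, ...) {
  cl <- object$clusters
  par_cols <- her_free_names()
  sols <- object$solutions
  retained <- cl$retained
  conv_rows <- object$conv_index[retained]
  par_mat <- as.matrix(sols[conv_rows, par_cols, drop = FALSE])
  spread <- apply(par_mat, 2, function(v) {
    if (all(v > 0)) diff(range(log10(v))) else diff(range(v))
  })
  reps <- object$conv_index[cl$representatives]
  out <- list(
    n_starts = object$n_starts,
    n_converged = length(object$conv_index),
    best_rmse = object$best_rmse,
    rmse_range = range(sols$rmse[object$conv_index]),
    k = cl$k,
    cluster_sizes = if (cl$k > 1) table(cl$labels) else length(retained),
    representatives = sols[reps, c("start", "rmse", par_cols)],
    log10_spread = sort(spread, decreasing = TRUE),
    best = object$best
  )
  class(out) <- "summary.her_fit"
  out
}

#' @export
print.summary.her_fit <- function(x, ...) {
  cat(sprintf(
    "HER model fit: %d/%d converged, best RMSE %.4g (range %.4g-%.4g)\n",
    x$n_converged, x$n_starts, x$best_rmse,
    x$rmse_range[1], x$rmse_range[2]))
  cat(sprintf("Clusters: k = %d;  sizes: %s\n", x$k,
              paste(x$cluster_sizes, collapse = ", ")))
  cat("Widest parameter spreads across retained solutions (decades):\n")
  print(round(utils::head(x$log10_spread, 8), 2))
  cat("Best-fit free parameters:\n")
  print(signif(x$best, 3))
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object A `her_fit` object.
#' @param representative `"best"` for the overall minimum-RMSE solution,
#'   or a cluster number for that cluster's representative.
#' @param ... Unused.
#' @return Named numeric vector of the 47 free parameters.
#' @export
coef.her_fit <- function(object, representative = "best", ...) {
  if (identical(representative, "best")) return(object$best)
  k <- as.integer(representative)
  if (is.na(k) || k < 1L || k > object$clusters$k)
    stop("representative must be 'best' or a cluster index in 1..",
         object$clusters$k, call. = FALSE)
  row <- object$conv_index[object$clusters$representatives[k]]
  unlist(object$solutions[row, her_free_names()])
}

#' Parameter set of a fitted model
#'
#' The template parameter set with a chosen solution's free values
#' substituted.
#'
#' @inheritParams coef.her_fit
#' @return A [her_parameters()] object.
#' @export
her_fit_parameters <- function(object, representative = "best") {
  her_set_free(object$params_template,
               coef(object, representative = representative))
}

#' Predict observables from a fitted model
#'
#' @param object A `her_fit` object.
#' @param newdata Design records (`cell_line`, `egf_ng_ml`, `hrg_ng_ml`,
#'   `block`, `time_min`, `measurement`); defaults to the fitted dataset.
#' @param representative Solution to predict with (see [coef.her_fit()]).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per record.
#' @export
predict.her_fit <- function(object, newdata = NULL,
                            representative = "best", ...) {
  if (is.null(newdata)) newdata <- object$data
  her_predict_design(newdata,
                     her_fit_parameters(object, representative),
                     object$profiles)
}

#' @export
residuals.her_fit <- function(object, representative = "best", ...) {
  pred <- predict(object, representative = representative)
  her_residuals_scaled(object$data, pred, object$scales)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new synthetic datasets with the fitted parameters as ground
#' truth, using the design (conditions and replicate structure) of the
#' fitted data.
#'
#' @param object A `her_fit` object.
#' @param nsim Number of datasets.
#' @param seed RNG seed.
#' @param cv Noise CV (defaults to 0.1).
#' @param ... Unused.
#' @return A list of `her_dataset` objects (length `nsim`).
#' @export
simulate.her_fit <- function(object, nsim = 1, seed = 1L, cv = 0.1, ...) {
  design <- unique(object$data[, c("cell_line", "egf_ng_ml", "hrg_ng_ml",
                                   "block", "time_min", "measurement")])
  design$replicates <- 2L
  class(design) <- c("her_design", "data.frame")
  pars <- her_fit_parameters(object)
  lapply(seq_len(nsim), function(i)
    her_synthesize(design, pars, cv = cv, seed = seed + i - 1L,
                   profiles = object$profiles))
}

#' Plot observed versus fitted values
#'
#' One panel per measurement class (total phospho, internal phospho,
#' mass): observed values against model predictions with the identity
#' line.
#'
#' @param x A `her_fit` object.
#' @param representative Solution to plot (see [coef.her_fit()]).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, a data.frame of observed and fitted values.
#' @export
plot.her_fit <- function(x, representative = "best", ...) {
  pred <- predict(x, representative = representative)
  df <- data.frame(measurement = x$data$measurement,
                   observed = x$data$value, fitted = pred)
  cls <- list(`total phospho` = c("pR1t", "pR2t", "pR3t"),
              `internal phospho` = c("pR1i", "pR2i", "pR3i"),
              `receptor mass` = c("mR1t", "mR2t", "mR3t"))
  old <- par(mfrow = c(1, length(cls)))
  on.exit(par(old))
  for (nm in names(cls)) {
    sub <- df[df$measurement %in% cls[[nm]], ]
    if (nrow(sub) == 0) next
    plot(sub$observed, sub$fitted, xlab = "observed", ylab = "fitted",
         main = nm, pch = 16, cex = 0.6,
         col = grDevices::hcl.colors(3, "Dark 3")[
           match(sub$measurement, cls[[nm]])], ...)
    abline(0, 1, lty = 2)
  }
  invisible(df)
}
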