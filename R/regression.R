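# Multilinear regression linking downstream kinase activation (Erk, Akt)
# to receptor- or dimer-level phosphorylation predictors.
#
# Two forms are supported, mirroring the two predictor granularities:
#   receptor mode:  pT(t) = b0 + sum_i  b_i   * pR_i(t)
#   dimer mode:     pT(t) = b0 + sum_ij b_iji * pR_iji(t)
# where pT is phospho-Erk or phospho-Akt, pR_i the total phosphorylation
# of receptor i and pR_iji the contribution of dimer Rij to receptor i's
# phosphorylation.

#' Fit a multilinear regression of kinase activation on HER phospho-signals
#'
#' Ordinary least squares of a downstream target (phospho-Erk or
#' phospho-Akt) on receptor-level or dimer-level phosphorylation
#' predictors, with an intercept.  Predictors are z-scored by default so
#' coefficient magnitudes are comparable; predictor importance is the
#' absolute standardized coefficient.  Collinearity is diagnosed via the
#' design-matrix condition number; a rank-deficient design is fitted with
#' the minimum-norm least-squares solution (via the pseudoinverse) and
#' flagged.
#'
#' @param data Data.frame containing the target column and predictor
#'   columns (rows = conditions/time points).
#' @param target Name of the target column (e.g. `"pErk"`, `"pAkt"`).
#' @param predictors Character vector of predictor column names; defaults
#'   to every numeric column except the target.
#' @param mode Label for the predictor granularity: `"receptor"` or
#'   `"dimer"`.  Purely descriptive; the design is taken from
#'   `predictors`.
#' @param standardize Z-score the predictors (default `TRUE`; the target
#'   is never transformed).
#' @return An object of class `her_regression`: coefficients (on the
#'   scale actually fitted, plus back-transformed raw-scale slopes when
#'   standardized), `r_squared`, `condition_number`, `rank_deficient`,
#'   `importance` (predictors sorted by absolute standardized
#'   coefficient), `fitted`, `residuals`.
#' @export
her_regression <- function(data, target,
                           predictors = NULL,
                           mode = c("receptor", "dimer"),
                           standardize = TRUE) {
  mode <- match.arg(mode)
  if (!target %in% names(data))
    stop("target column '", target, "' not found", call. = FALSE)
  if (is.null(predictors)) {
    num <- vapply(data, is.numeric, logical(1))
    predictors <- setdiff(names(data)[num], target)
  }
  miss <- setdiff(predictors, names(data))
  if (length(miss) > 0)
    stop("predictor column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- data[[target]]
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (nrow(X) < length(predictors) + 1L)
    stop("need at least ", length(predictors) + 1L,
         " observations for ", length(predictors), " predictors",
         call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (standardize) {
    scl[scl == 0] <- 1           # constant columns: leave centred at 0
    Xf <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  } else {
    Xf <- X
  }
  D <- cbind(`(Intercept)` = 1, Xf)
  qrD <- qr(D)
  rank_def <- qrD$rank < ncol(D)
  if (!rank_def) {
    fit <- lm.fit(D, y)
    beta <- fit$coefficients
  } else {
    # minimum-norm solution via the pseudoinverse
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- stats::setNames(as.vector(beta), colnames(D))
    warning("rank-deficient design; returning the minimum-norm solution",
            call. = FALSE)
  }
  fitted <- as.vector(D %*% beta)
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  slopes <- beta[-1L]
  raw_slopes <- if (standardize) slopes / scl else slopes
  raw_intercept <- if (standardize)
    beta[[1L]] - sum(raw_slopes * ctr) else beta[[1L]]
  imp <- sort(abs(if (standardize) slopes else slopes * apply(X, 2, sd)),
              decreasing = TRUE)
  structure(list(
    target = target, mode = mode, standardize = standardize,
    coefficients = beta,
    raw_coefficients = c(`(Intercept)` = raw_intercept, raw_slopes),
    r_squared = r2,
    condition_number = kappa(D, exact = TRUE),
    rank_deficient = rank_def,
    importance = imp,
    fitted = fitted, residuals = res,
    n = length(y)
  ), class = "her_regression")
}

#' @export
print.her_regression <- function(x, ...) {
  cat(sprintf("Multilinear regression of %s on %d %s-level predictor(s)\n",
              x$target, length(x$coefficients) - 1L, x$mode))
  cat(sprintf("  R^2 = %.4f;  condition number %.3g%s\n", x$r_squared,
              x$condition_number,
              if (x$rank_deficient) "  [rank deficient: minimum-norm fit]"
              else ""))
  cat("  coefficients",
      if (x$standardize) "(standardized predictors):" else ":", "\n")
  print(signif(x$coefficients, 4))
  cat("  dominant predictor:", names(x$importance)[1], "\n")
  invisible(x)
}

#' @export
coef.her_regression <- function(object, raw = FALSE, ...) {
  if (raw) object$raw_coefficients else object$coefficients
}

#' @export
predict.her_regression <- function(object, newdata, ...) {
  b <- object$raw_coefficients
  X <- as.matrix(newdata[, names(b)[-1L], drop = FALSE])
  as.vector(b[[1L]] + X %*% b[-1L])
}

#' @export
residuals.her_regression <- function(object, ...) object$residuals
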