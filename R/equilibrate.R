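# Pre-stimulation equilibration.
#
# Before ligand addition the only complexes are constitutive HER2
# homodimers; HER1 and HER3 exist purely as monomers distributed across
# the three compartments by synthesis, internalization, recycling and
# degradation.  Synthesis rates are solved so that the total copy number
# of each receptor at steady state matches the cell line's expression.

# closed-form ligand-free steady state of a single monomer species:
# surface S, endosomal E, late-endosomal L with
#   0 = syn - kt S + kr E;  0 = kt S - (kr+kl) E;  0 = kl E - kd L
.monomer_steady <- function(total, kt, kr, kl, kd) {
  if (total <= 0) {
    return(list(s = 0, e = 0, l = 0, syn = 0))
  }
  if (kt <= 0) {
    # no internalization: everything sits at the surface, no turnover
    return(list(s = total, e = 0, l = 0, syn = 0))
  }
  fe <- kt / (kr + kl)          # E = fe * S
  fl <- kl * fe / kd            # L = fl * S
  s <- total / (1 + fe + fl)
  e <- fe * s
  l <- fl * s
  list(s = s, e = e, l = l, syn = kl * e)  # synthesis balances degradation
}

# monomer trafficking rates for one receptor (from the species table)
.monomer_rates <- function(params, receptor = c("R1", "R2", "R3")) {
  receptor <- match.arg(receptor)
  tr <- .species_trafficking(params)
  tr[tr$name == receptor, ]
}

# ligand-free HER2 steady state with constitutive R22 homodimerization.
# Unknowns u = log(R2s, R2e, R22s, R22e); LE pools and the synthesis rate
# follow algebraically.  Solved by damped Newton with a finite-difference
# Jacobian; returns NULL on failure (caller falls back to integration).
.her2_steady_newton <- function(params, total) {
  trm <- .monomer_rates(params, "R2")
  trd <- .species_trafficking(params)
  trd <- trd[trd$name == "R22", ]
  kcs <- params$kc[["s"]]
  kce <- params$kc[["e"]] * params$ee_volume_factor
  kus <- params$ku[["ku22s"]]
  kue <- params$ku[["ku22i"]]
  resid <- function(u) {
    x <- exp(u)
    r2s <- x[1]; r2e <- x[2]; d2s <- x[3]; d2e <- x[4]
    c(kcs * r2s^2 - (kus + trd$kint) * d2s + trd$kr * d2e,
      trm$kint * r2s - (trm$kr + trm$kl) * r2e - 2 * kce * r2e^2 +
        2 * kue * d2e,
      kce * r2e^2 + trd$kint * d2s - (kue + trd$kr + trd$kl) * d2e,
      r2s + r2e + trm$kl * r2e / trm$kd +
        2 * (d2s + d2e + trd$kl * d2e / trd$kd) - total)
  }
  ms <- .monomer_steady(total, trm$kint, trm$kr, trm$kl, trm$kd)
  d2s0 <- max(kcs * ms$s^2 / (kus + trd$kint + 1e-12), 1e-8)
  u <- log(pmax(c(ms$s, ms$e, d2s0, d2s0 * trd$kint /
                    (kue + trd$kr + trd$kl + 1e-12)), 1e-10))
  scale <- max(total, 1)
  for (it in 1:60) {
    f <- resid(u)
    if (max(abs(f)) / scale < 1e-12) break
    J <- matrix(0, 4, 4)
    h <- 1e-7
    for (j in 1:4) {
      uj <- u; uj[j] <- uj[j] + h
      J[, j] <- (resid(uj) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damp: cap log-step to keep Newton in its basin
    step <- pmin(pmax(step, -2), 2)
    u <- u - step
    if (it == 60L) return(NULL)
  }
  x <- exp(u)
  f <- resid(u)
  if (max(abs(f)) / scale > 1e-8) return(NULL)
  syn <- trm$kint * x[1] - trm$kr * x[2] + 2 * kcs * x[1]^2 - 2 * kus * x[3]
  if (!is.finite(syn) || syn < 0) return(NULL)
  list(r2 = c(s = x[1], e = x[2], l = trm$kl * x[2] / trm$kd),
       r22 = c(s = x[3], e = x[4], l = trd$kl * x[4] / trd$kd),
       syn = syn)
}

#' Equilibrate a cell line to its pre-stimulation steady state
#'
#' Solves the ligand-free steady state of a cell-line profile and the
#' surface synthesis rates that sustain it, so that the total copy number
#' of each receptor (counting homodimer members individually) equals the
#' profile expression.  HER1 and HER3 distributions are closed-form
#' (linear three-compartment balance).  HER2 participates in constitutive
#' homodimerization, so its synthesis rate is refined by a fixed-point
#' loop: integrate the ligand-free model to steady state, rescale the
#' synthesis rate by the ratio of target to achieved total, and repeat.
#'
#' @param profile A cell-line profile (see [her_profile()]).
#' @param params A [her_parameters()] object.
#' @param tol Relative tolerance on total receptor copies (default 1e-5;
#'   well inside the 0.1% contract) and on the steady-state residual.
#' @param max_iter Maximum fixed-point iterations for the HER2 branch.
#' @return An object of class `her_equilibrium`: list with `state` (named
#'   51-vector), `params` (synthesis rates filled in), `profile`,
#'   `totals` (achieved copies per receptor), `residual_norm` (max
#'   absolute RHS element relative to the largest state entry) and
#'   `iterations`.
#' @export
her_equilibrate <- function(profile, params = her_parameters(),
                            tol = 1e-5, max_iter = 30L) {
  stopifnot(inherits(params, "her_parameters"))
  state <- stats::setNames(numeric(.n_state), her_state_names())
  syn <- c(R1 = 0, R2 = 0, R3 = 0)
  for (rec in c("R1", "R3")) {
    tr <- .monomer_rates(params, rec)
    tot <- if (rec == "R1") profile$her1 else profile$her3
    ms <- .monomer_steady(tot, tr$kint, tr$kr, tr$kl, tr$kd)
    state[.state_index(rec, "s")] <- ms$s
    state[.state_index(rec, "e")] <- ms$e
    state[.state_index(rec, "l")] <- ms$l
    syn[rec] <- ms$syn
  }
  tr2 <- .monomer_rates(params, "R2")
  ms2 <- .monomer_steady(profile$her2, tr2$kint, tr2$kr, tr2$kl, tr2$kd)
  state[.state_index("R2", "s")] <- ms2$s
  state[.state_index("R2", "e")] <- ms2$e
  state[.state_index("R2", "l")] <- ms2$l
  syn["R2"] <- ms2$syn
  iterations <- 0L

  if (profile$her2 > 0 && params$kc[["s"]] > 0) {
    # constitutive R22 formation couples the HER2 balance nonlinearly;
    # solve it by Newton, falling back to an integrate-and-rescale fixed
    # point if Newton leaves its basin
    nw <- .her2_steady_newton(params, profile$her2)
    if (!is.null(nw)) {
      for (cp in c("s", "e", "l")) {
        state[.state_index("R2", cp)] <- nw$r2[[cp]]
        state[.state_index("R22", cp)] <- nw$r22[[cp]]
      }
      syn["R2"] <- nw$syn
    } else {
      horizon <- 4000
      repeat {
        iterations <- iterations + 1L
        params$synthesis <- syn
        sol <- .integrate_states(state, params, times = c(0, horizon))
        state_new <- sol[nrow(sol), -1L]
        names(state_new) <- her_state_names()
        tot2 <- her_receptor_totals(state_new)[["R2"]]
        err <- abs(tot2 - profile$her2) / profile$her2
        drift <- max(abs(state_new - state)) /
          max(max(abs(state_new)), 1)
        state <- state_new
        if ((err < tol && drift < 1e-6) || iterations >= max_iter) {
          if (err >= tol)
            warning(sprintf(
              "HER2 equilibration reached %d iterations (rel. error %.2g)",
              iterations, err))
          break
        }
        syn["R2"] <- syn[["R2"]] * profile$her2 / tot2
        horizon <- min(horizon * 1.5, 20000)
      }
    }
  }
  params$synthesis <- syn
  rhs <- .rhs_compiled_eval(state, params)
  scale <- max(max(abs(state)), 1)
  structure(list(
    state = state,
    params = params,
    profile = profile,
    totals = her_receptor_totals(state),
    synthesis = syn,
    residual_norm = max(abs(rhs)) / scale,
    iterations = iterations
  ), class = "her_equilibrium")
}

#' Total receptor copies per type in a state vector
#'
#' Counts every copy of each receptor across all species and compartments;
#' homodimer members count twice.
#'
#' @param state Named state vector of length 51.
#' @return Named vector `c(R1=, R2=, R3=)`.
#' @export
her_receptor_totals <- function(state) {
  sp <- .species_table()
  copies <- cbind(sp$n1, sp$n2, sp$n3)
  x <- matrix(state, nrow = .n_species)   # species x compartment
  stats::setNames(as.vector(t(copies) %*% rowSums(x)),
                  c("R1", "R2", "R3"))
}

#' @export
print.her_equilibrium <- function(x, ...) {
  cat(sprintf("Pre-stimulation steady state for '%s'\n", x$profile$name))
  t <- x$totals
  cat(sprintf("  total copies  HER1 %.0f  HER2 %.0f  HER3 %.0f\n",
              t[["R1"]], t[["R2"]], t[["R3"]]))
  cat(sprintf("  synthesis (molecules/cell/min)  R1 %.2f  R2 %.2f  R3 %.2f\n",
              x$synthesis[["R1"]], x$synthesis[["R2"]], x$synthesis[["R3"]]))
  cat(sprintf("  relative steady-state residual %.2e (%d iterations)\n",
              x$residual_norm, x$iterations))
  invisible(x)
}

# low-level integration of the compiled model
.integrate_states <- function(state, params, times,
                              rtol = 1e-8, atol = 1e-10) {
  parms <- .build_parms(params)
  out <- deSolve::lsoda(y = unname(state), times = times, func = "derivs",
                        parms = parms, dllname = "herdimer",
                        initfunc = "initparms", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed at t = ",
         out[nrow(out), 1L], call. = FALSE)
  out
}
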