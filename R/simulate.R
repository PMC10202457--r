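# ODE integration and the clearance readout.

#' Percent reporter cleared from the cytosol, from a state vector
#'
#' clearance = 100 x (Z_total - free reporter) / Z_total. In the model the
#' cytosolic reporter pool is the free species N2; everything else is bound
#' to membrane receptors, so this is the model counterpart of the imaging
#' readout (percent drop of cytosolic reporter fluorescence).
#'
#' @param state numeric vector of 16 concentrations (M).
#' @param index species catalogue.
#' @param Ztotal total reporter concentration (M, > 0).
#' @return clearance in percent.
#' @examples
#' eq <- analyticPrestimulusState(modelParameters())
#' clearanceFromState(equilibriumState(eq), Ztotal = reporterTotal(modelParameters()))
#' @export
clearanceFromState <- function(state, index = speciesIndex(),
                               Ztotal) {
  if (Ztotal <= 0) stop("Ztotal must be positive")
  free <- as.numeric(state)[which(index$is_free_reporter)]
  100 * (Ztotal - free) / Ztotal
}

#' Simulate a stimulation timecourse
#'
#' Integrates the network from the analytic pre-stimulus state with the
#' ligand concentration clamped at its dose-converted value from t = 0.
#' Uses a stiff-capable adaptive solver (deSolve::lsoda) at rtol 1e-8 /
#' atol 1e-14 M on a fixed output grid, and attaches the clearance readout.
#' Identical inputs and solver settings give bit-identical trajectories.
#'
#' @param params a [ModelParameters-class] (base, unscaled rates).
#' @param ligand a [LigandSpec-class]; its beta/gamma are applied to k7/k3
#'   and its dose sets the clamped ligand concentration.
#' @param duration simulated horizon in seconds (default 30 min).
#' @param outputStep output grid step in seconds.
#' @param rtol,atol solver tolerances.
#' @param network a [ReactionNetwork-class].
#' @return a [Trajectory-class].
#' @examples
#' tr <- simulateTimecourse(modelParameters(), ligandSpec("EGF", dose = 20),
#'                          duration = 300)
#' tail(clearance(tr), 1)
#' @export
simulateTimecourse <- function(params, ligand, duration = 1800,
                               outputStep = 5, rtol = 1e-8, atol = 1e-14,
                               network = reactionNetwork()) {
  stopifnot(is(params, "ModelParameters"), is(ligand, "LigandSpec"))
  scaled <- applyLigandScaling(params, ligand)
  L <- ligandConcentration(ligand)
  eq <- analyticPrestimulusState(scaled, network)
  y0 <- equilibriumState(eq)
  y0["N1"] <- L
  rd <- .rhsData(scaled, network)
  times <- seq(0, duration, by = outputStep)
  func <- function(t, y, p) list(.rhs(y, rd))
  sol <- deSolve::lsoda(y = y0, times = times, func = func, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf(
      "solver failed (istate %d) at rtol=%g atol=%g duration=%g dose=%g",
      attr(sol, "istate")[1L], rtol, atol, duration, ligand@dose))
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- network@species$label
  if (min(states) < -1e3 * atol)
    stop("negative concentrations beyond tolerance; solver settings unsuitable")
  states[states < 0] <- 0
  Zt <- scaled@reporterTotal
  clr <- if (Zt > 0) 100 * (Zt - states[, "N2"]) / Zt else rep(0, nrow(states))
  # drift check against the initial conserved totals
  w <- .conservationWeights(network@species)
  rec <- states %*% w$receptor
  rep_ <- states %*% w$reporter
  drift <- max(abs(rec - rec[1]) / max(rec[1], atol),
               abs(rep_ - rep_[1]) / max(rep_[1], atol))
  new("Trajectory", times = times, states = states, clearance = as.numeric(clr),
      metadata = list(params = params, ligand = ligand,
                      scaledRates = scaled@rates,
                      ligandConc = L, duration = duration,
                      outputStep = outputStep, rtol = rtol, atol = atol,
                      solver = "lsoda", conservationDrift = drift,
                      equilibrium = c(N3o = eq@N3o, N5o = eq@N5o)))
}

#' Fixed-step RK4 reference trajectory
#'
#' Brute-force reference integrator (classical Runge-Kutta, default 1 ms
#' step, compiled) used to validate the adaptive solver. Same initial state
#' and readout as [simulateTimecourse()].
#'
#' @inheritParams simulateTimecourse
#' @param dt fixed step in seconds.
#' @return a [Trajectory-class].
#' @export
rk4Reference <- function(params, ligand, duration = 1800, outputStep = 5,
                         dt = 1e-3, network = reactionNetwork()) {
  stopifnot(is(params, "ModelParameters"), is(ligand, "LigandSpec"))
  scaled <- applyLigandScaling(params, ligand)
  L <- ligandConcentration(ligand)
  eq <- analyticPrestimulusState(scaled, network)
  y0 <- equilibriumState(eq)
  y0["N1"] <- L
  rd <- .rhsData(scaled, network)
  S <- rd$S
  nz <- which(S != 0, arr.ind = TRUE)
  times <- seq(0, duration, by = outputStep)
  states <- .rk4_integrate(unname(y0), times, dt, rd$km,
                           as.integer(rd$r1),
                           as.integer(ifelse(rd$r2 == 17L, 0L, rd$r2)),
                           as.integer(nz[, 1]), as.integer(nz[, 2]),
                           as.numeric(S[nz]), 1L)
  colnames(states) <- network@species$label
  Zt <- scaled@reporterTotal
  clr <- if (Zt > 0) 100 * (Zt - states[, "N2"]) / Zt else rep(0, nrow(states))
  new("Trajectory", times = times, states = states,
      clearance = as.numeric(clr),
      metadata = list(params = params, ligand = ligand, dt = dt,
                      solver = "rk4", duration = duration,
                      outputStep = outputStep))
}

#' @rdname Trajectory-accessors
#' @name Trajectory-accessors
#' @title Accessors for Trajectory objects
#' @param trajectory a [Trajectory-class].
#' @return `timePoints`: the output grid (s); `speciesStates`: the time x
#'   species concentration matrix (M); `clearance`: the percent-cleared
#'   readout.
#' @export
timePoints <- function(trajectory) trajectory@times

#' @rdname Trajectory-accessors
#' @export
speciesStates <- function(trajectory) trajectory@states

#' @rdname Trajectory-accessors
#' @export
clearance <- function(trajectory) trajectory@clearance

setMethod("show", "Trajectory", function(object) {
  md <- object@metadata
  lig <- md$ligand
  cat(sprintf("Trajectory: %d time points over %.4g s (%s)\n",
              length(object@times), max(object@times),
              md$solver %||% "?"))
  if (!is.null(lig))
    cat(sprintf("  ligand '%s' dose %g ng/mL (beta %g, gamma %g)\n",
                lig@name, lig@dose, lig@beta, lig@gamma))
  cat(sprintf("  final clearance %.3g%%", tail(object@clearance, 1)))
  if (!is.null(md$conservationDrift))
    cat(sprintf(" | conservation drift %.2g", md$conservationDrift))
  cat("\n")
})
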