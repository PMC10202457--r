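# Simulation experiments: dose panels, kinetic regime classification,
# the GBM-mutant scenario, expression-ratio sweeps and the k6 scan.

.defaultDoses <- c(0, 0.2, 2, 20, 200, 2000, 5000)  # ng/mL, log-spaced panel

#' Simulate a (beta, gamma) x dose panel of responses
#'
#' One trajectory per combination of beta, gamma and dose. The default
#' values (beta in {1, 1000}, gamma in {1, 100}, doses 0-5000 ng/mL)
#' reproduce the four-panel structure used to separate the effects of
#' ligand-binding affinity from ligand-bound dimerization affinity.
#'
#' @param params a [ModelParameters-class].
#' @param beta,gamma vectors of scale factors (> 0).
#' @param doses vector of doses in ng/mL.
#' @param duration horizon in seconds.
#' @param ... passed to [simulateTimecourse()].
#' @return a list with `grid` (data.frame of beta, gamma, dose and summary
#'   columns) and `trajectories` (list of [Trajectory-class], same order).
#' @export
doseResponsePanel <- function(params, beta = c(1, 1000), gamma = c(1, 100),
                              doses = .defaultDoses, duration = 1800, ...) {
  if (!length(beta) || !length(gamma) || !length(doses))
    stop("beta, gamma and doses must be nonempty")
  grid <- expand.grid(dose = doses, gamma = gamma, beta = beta,
                      KEEP.OUT.ATTRS = FALSE)[, c("beta", "gamma", "dose")]
  net <- reactionNetwork()
  trajs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lig <- ligandSpec(name = sprintf("b%g_g%g", grid$beta[i], grid$gamma[i]),
                      dose = grid$dose[i], beta = grid$beta[i],
                      gamma = grid$gamma[i])
    trajs[[i]] <- simulateTimecourse(params, lig, duration = duration,
                                     network = net, ...)
  }
  grid$finalClearance <- vapply(trajs, function(tr) tail(clearance(tr), 1), 0)
  grid$tHalf <- vapply(trajs, function(tr) {
    th <- try(timeToHalfMax(clearance(tr), timePoints(tr)), silent = TRUE)
    if (inherits(th, "try-error")) NA_real_ else th$time
  }, 0)
  grid$regime <- vapply(trajs, function(tr) classifyKinetics(tr)@label, "")
  list(grid = grid, trajectories = trajs)
}

#' Classify the kinetic regime of a clearance trajectory
#'
#' Deterministic operationalization of the qualitative regimes: `flat`
#' (no response), `peak-plateau` (early transient maximum exceeding the
#' final level, settled well before the end), `biphasic-rising` (monotone,
#' with a fast sub-2-min phase followed by a persistent slow rise) and
#' `gradual-rising` (everything else). All thresholds are exposed.
#'
#' Rules, evaluated in order on the clearance series c(t) with final value
#' cEnd at `horizon` (default 30 min):
#' \enumerate{
#'   \item flat: cEnd < `flatPct` (percent of the reporter pool).
#'   \item peak-plateau: max over t <= `earlyWindow` >= `peakRatio` x cEnd
#'     and c(`earlyWindow`) >= `settleFrac` x cEnd.
#'   \item biphasic-rising: monotone within `monotoneTol` percent points,
#'     mean slope on [0, `fastWindow`] >= `slopeFactor` x mean slope on
#'     [`lateStart`, horizon] > 0, and cEnd >= `riseRatio` x
#'     c(`earlyWindow`).
#'   \item otherwise gradual-rising.
#' }
#'
#' @param trajectory a [Trajectory-class] covering at least `horizon`
#'   seconds.
#' @param horizon evaluation endpoint (s).
#' @param flatPct flat threshold, percent cleared.
#' @param earlyWindow end of the early window (s).
#' @param peakRatio overshoot ratio for peak-plateau.
#' @param settleFrac fraction of the final value reached by `earlyWindow`.
#' @param monotoneTol tolerated decrease (percent points) for monotonicity.
#' @param fastWindow end of the fast-phase window (s).
#' @param lateStart start of the late window (s).
#' @param slopeFactor required early/late slope ratio.
#' @param riseRatio required cEnd / c(earlyWindow) for a persistent rise.
#' @return a [RegimeLabel-class].
#' @export
classifyKinetics <- function(trajectory, horizon = 1800, flatPct = 1,
                             earlyWindow = 300, peakRatio = 1.02,
                             settleFrac = 0.90, monotoneTol = 0.5,
                             fastWindow = 120, lateStart = 600,
                             slopeFactor = 5, riseRatio = 1.10) {
  stopifnot(is(trajectory, "Trajectory"))
  tt <- trajectory@times
  cc <- trajectory@clearance
  if (max(tt) < horizon)
    stop(sprintf("trajectory too short: %.4g s < horizon %.4g s", max(tt),
                 horizon))
  at <- function(t0) approx(tt, cc, xout = t0, rule = 2)$y
  cEnd <- at(horizon)
  early <- cc[tt <= earlyWindow]
  peakEarly <- max(early)
  overshoot <- if (cEnd > 0) peakEarly / cEnd else NA_real_
  earlySlope <- (at(fastWindow) - at(0)) / fastWindow
  lateSlope <- (cEnd - at(lateStart)) / (horizon - lateStart)
  tHalf <- tryCatch(timeToHalfMax(cc[tt <= horizon], tt[tt <= horizon])$time,
                    error = function(e) NA_real_)
  diag <- list(early_slope = earlySlope, late_slope = lateSlope,
               t_half = tHalf, overshoot_ratio = overshoot,
               final = cEnd, peak_early = peakEarly,
               thresholds = list(flatPct = flatPct, peakRatio = peakRatio,
                                 settleFrac = settleFrac,
                                 monotoneTol = monotoneTol,
                                 slopeFactor = slopeFactor,
                                 riseRatio = riseRatio))
  label <-
    if (cEnd < flatPct) {
      "flat"
    } else if (peakEarly >= peakRatio * cEnd &&
               at(earlyWindow) >= settleFrac * cEnd) {
      "peak-plateau"
    } else {
      keep <- tt <= horizon
      monotone <- all(cc[keep] >= cummax(cc[keep]) - monotoneTol)
      if (monotone && lateSlope > 0 &&
          earlySlope >= slopeFactor * lateSlope &&
          cEnd >= riseRatio * at(earlyWindow)) {
        "biphasic-rising"
      } else "gradual-rising"
    }
  new("RegimeLabel", label = label, diagnostics = diag)
}

setMethod("show", "RegimeLabel", function(object) {
  d <- object@diagnostics
  cat(sprintf("RegimeLabel '%s' (tHalf %.3g s, overshoot %.3g, early/late slope %.3g)\n",
              object@label, d$t_half, d$overshoot_ratio,
              if (is.finite(d$late_slope) && d$late_slope != 0)
                d$early_slope / d$late_slope else NA))
})

#' Simulate wild-type vs GBM-mutant receptor responses to a low-affinity ligand
#'
#' Wild-type receptor stimulated with EREG is modeled as beta = 50,
#' gamma = 100 relative to the EGF base case. The GBM-associated
#' extracellular mutations strengthen dimerization of low-affinity-ligand-
#' bound receptors ~650-fold while changing ligand binding only ~6-fold, so
#' the mutant is simulated with beta = 6 and gamma = 100/650 relative to
#' the base case (i.e. 650-fold stronger dimerization than the wild type
#' bound to EREG). Setting `literalScaling = TRUE` instead multiplies the
#' wild-type EREG gamma by 650 (a 650-fold *weaker* dimerization), which
#' reverses the predicted phenotype; it is retained for comparison only.
#'
#' @param params a [ModelParameters-class].
#' @param dose EREG dose in ng/mL (default 20).
#' @param literalScaling use the literal "increase gamma 650-fold" reading.
#' @param ... passed to [simulateTimecourse()].
#' @return list with `wt` and `gbm` [Trajectory-class] objects and
#'   `ligands`, the two [LigandSpec-class]s used.
#' @export
simulateGbmScenario <- function(params, dose = 20, literalScaling = FALSE,
                                ...) {
  wtLig <- ligandSpec("EREG-WT", dose = dose, beta = 50, gamma = 100)
  gbmGamma <- if (literalScaling) 100 * 650 else 100 / 650
  gbmLig <- ligandSpec("EREG-GBM", dose = dose, beta = 6, gamma = gbmGamma)
  list(wt = simulateTimecourse(params, wtLig, ...),
       gbm = simulateTimecourse(params, gbmLig, ...),
       ligands = list(wt = wtLig, gbm = gbmLig))
}

#' Sweep the receptor:reporter expression ratio
#'
#' Computes the end-of-run percent translocation of the reporter as a
#' function of the receptor:reporter ratio. By default the reporter total
#' is varied at fixed receptor total (`vary = "reporter"`): with reporter
#' in excess the bound fraction is exactly proportional to the ratio
#' (linear regime), and once the reporter pool drops below the active
#' receptor pool the translocation saturates. `vary = "receptor"` is also
#' available and recorded in the output.
#'
#' @param params a [ModelParameters-class].
#' @param ratios positive receptor:reporter ratios.
#' @param dose ligand dose in ng/mL (default saturating EGF).
#' @param duration horizon (s).
#' @param vary which total to vary: "reporter" (default) or "receptor".
#' @param ligand optional [LigandSpec-class] template (its dose is
#'   overridden).
#' @param ... passed to [simulateTimecourse()].
#' @return data.frame with columns ratio, receptorTotal, reporterTotal,
#'   translocation (percent); attribute `vary` records the mode.
#' @export
expressionRatioSweep <- function(params, ratios = 10^seq(-1, 1, length.out = 16),
                                 dose = 5000, duration = 1800,
                                 vary = c("reporter", "receptor"),
                                 ligand = NULL, ...) {
  vary <- match.arg(vary)
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (is.null(ligand)) ligand <- ligandSpec("EGF")
  ligand@dose <- dose
  net <- reactionNetwork()
  out <- data.frame(ratio = ratios, receptorTotal = NA_real_,
                    reporterTotal = NA_real_, translocation = NA_real_)
  for (i in seq_along(ratios)) {
    p <- if (vary == "reporter") {
      updateParameters(params,
                       reporterTotal = params@receptorTotal / ratios[i])
    } else {
      updateParameters(params,
                       receptorTotal = params@reporterTotal * ratios[i])
    }
    tr <- simulateTimecourse(p, ligand, duration = duration, network = net,
                             ...)
    out$receptorTotal[i] <- p@receptorTotal
    out$reporterTotal[i] <- p@reporterTotal
    out$translocation[i] <- tail(clearance(tr), 1)
  }
  attr(out, "vary") <- vary
  out
}

#' Scan the ligand-free dimer dissociation rate k6
#'
#' Re-simulates a stimulation timecourse for each k6 value and summarizes
#' each trajectory (pre-stimulus dimer pool, final clearance, time to
#' half-max, regime). The pre-stimulus dimer pool N5o decreases
#' monotonically as k6 grows.
#'
#' @param params a [ModelParameters-class].
#' @param values positive k6 values (1/s); the default spans two orders of
#'   magnitude around 5e-3.
#' @param ligand a [LigandSpec-class] (default 20 ng/mL EGF).
#' @param duration horizon (s).
#' @param ... passed to [simulateTimecourse()].
#' @return data.frame with one row per k6 value.
#' @export
scanK6 <- function(params, values = 5e-3 * 10^seq(-1, 1, length.out = 9),
                   ligand = ligandSpec("EGF", dose = 20), duration = 1800,
                   ...) {
  if (!length(values)) stop("values must be nonempty")
  if (any(values <= 0)) stop("k6 values must be positive")
  net <- reactionNetwork()
  rows <- lapply(values, function(v) {
    p <- updateParameters(params, k6 = v)
    tr <- simulateTimecourse(p, ligand, duration = duration, network = net,
                             ...)
    eqm <- tr@metadata$equilibrium
    th <- tryCatch(timeToHalfMax(clearance(tr), timePoints(tr))$time,
                   error = function(e) NA_real_)
    data.frame(k6 = v, N5o = unname(eqm["N5o"]),
               finalClearance = tail(clearance(tr), 1), tHalf = th,
               regime = classifyKinetics(tr, horizon = min(duration, 1800))@label)
  })
  do.call(rbind, rows)
}
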