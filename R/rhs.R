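# Mass-action right-hand side, generated from the declarative reaction list.

# Precompute the numeric ingredients of the RHS for a given (already
# ligand-scaled) parameter set: per-reaction effective rate constants
# (k * statistical multiplicity) and 0-padded reactant indices.
.rhsData <- function(params, network = reactionNetwork()) {
  rx <- network@reactions
  k <- params@rates[rx$rate]
  r2 <- rx$r2
  r2[is.na(r2)] <- 17L  # index of a padded 1.0 entry
  list(km = unname(k * rx$multiplicity),
       r1 = rx$r1, r2 = r2,
       S = network@stoichiometry)
}

# Fast internal RHS on a padded concentration vector; no validation.
.rhs <- function(conc, rd) {
  y <- c(conc, 1)
  rates <- rd$km * y[rd$r1] * y[rd$r2]
  d <- drop(rd$S %*% rates)
  d[1L] <- 0
  d
}

#' Mass-action derivative of the activation network
#'
#' Computes dN/dt (molar/s) for the 16 species at the given state. The free
#' ligand N1 is clamped: its concentration is set to `ligandConc` and its
#' reported derivative is zero. The derivative is generated from the
#' reaction list, so it is bilinear in the concentrations and exactly
#' orthogonal to the receptor and reporter conservation vectors.
#'
#' @param state numeric vector of 16 concentrations (M), ordered N1..N16
#'   (the N1 entry is ignored and replaced by `ligandConc`).
#' @param params a [ModelParameters-class]; apply ligand scaling first via
#'   [applyLigandScaling()] if beta/gamma differ from 1.
#' @param ligandConc free ligand concentration (M), held constant.
#' @param network a [ReactionNetwork-class] (rebuilt when omitted).
#' @return numeric vector of 16 derivatives (M/s), named N1..N16.
#' @examples
#' eq <- analyticPrestimulusState(modelParameters())
#' max(abs(massActionRHS(equilibriumState(eq), modelParameters(), 0)))
#' @export
massActionRHS <- function(state, params, ligandConc,
                          network = reactionNetwork()) {
  stopifnot(is(params, "ModelParameters"), length(state) == 16L)
  if (any(!is.finite(state)) || any(state < 0))
    stop("state concentrations must be finite and nonnegative")
  if (ligandConc < 0) stop("ligand concentration must be nonnegative")
  conc <- as.numeric(state)
  conc[1L] <- ligandConc
  rd <- .rhsData(params, network)
  d <- .rhs(conc, rd)
  names(d) <- network@species$label
  d
}

#' Conserved receptor and reporter totals of a state
#'
#' receptor total = sum over species of receptor_count x concentration;
#' reporter total = free reporter + sum of reporter_occupancy x
#' concentration. Both are invariants of the dynamics (ligand is clamped
#' and not conserved).
#'
#' @param state numeric vector of 16 concentrations (M).
#' @param index species catalogue from [speciesIndex()].
#' @return named numeric: `receptor_total`, `reporter_total` (M).
#' @examples
#' eq <- analyticPrestimulusState(modelParameters())
#' conservedTotals(equilibriumState(eq))
#' @export
conservedTotals <- function(state, index = speciesIndex()) {
  stopifnot(length(state) == 16L)
  state <- as.numeric(state)
  w <- .conservationWeights(index)
  c(receptor_total = sum(w$receptor * state),
    reporter_total = sum(w$reporter * state))
}

# Conservation weight vectors (receptor, reporter) used by tests and the
# simulator's drift check.
.conservationWeights <- function(index = speciesIndex()) {
  wRec <- as.numeric(index$receptor_count)
  wRep <- as.numeric(index$reporter_occupancy)
  wRep[index$is_free_reporter] <- 1
  list(receptor = wRec, reporter = wRep)
}
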