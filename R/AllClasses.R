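# S4 classes for the model side of the package. The trace container
# (CellTraceSet) lives in trace-set.R because it extends SummarizedExperiment.

#' ModelParameters: rate constants and totals of the receptor/reporter network
#'
#' Holds the seven mass-action rate constants of the activation network,
#' the total receptor and reporter concentrations, and the geometric
#' constants they derive from. Internal units are molar and seconds
#' throughout; doses in ng/mL are converted at the boundary
#' (see [doseToConcentration()]).
#'
#' Rate constant roles (first-order in 1/s, second-order in 1/M/s):
#' \describe{
#'   \item{k1}{ligand-receptor association (per free binding site)}
#'   \item{k2}{reporter association to a free tail of a ligand-bound dimer}
#'   \item{k3}{dissociation of ligand-bound dimers; scaled by gamma}
#'   \item{k4}{reporter dissociation (from any reporter-bound species)}
#'   \item{k5}{receptor dimerization forward rate, lumped with
#'     autophosphorylation (shared by ligand-free and ligand-bound pairs)}
#'   \item{k6}{dissociation of ligand-free (pre-formed, inactive) dimers}
#'   \item{k7}{ligand dissociation; scaled by beta}
#' }
#' Note an alternative reading exists in which k5/k7 are the forward/reverse
#' pair of the lumped ligand-induced dimerization step; the roles above are
#' the ones consistent with beta encoding ligand-binding affinity and gamma
#' encoding the dimerization affinity of ligand-bound receptors, and with
#' k6/k5 setting the pre-stimulus ligand-free dimer equilibrium.
#'
#' @slot rates named numeric, k1..k7.
#' @slot receptorTotal total receptor concentration (M).
#' @slot reporterTotal total reporter concentration (M); defaults to the
#'   receptor total (1:1 molar ratio).
#' @slot receptorsPerCell receptor copy number used to derive the total.
#' @slot cellRadius cell radius in micrometers (cell treated as a sphere).
#' @exportClass ModelParameters
setClass("ModelParameters",
  representation(
    rates = "numeric",
    receptorTotal = "numeric",
    reporterTotal = "numeric",
    receptorsPerCell = "numeric",
    cellRadius = "numeric"
  )
)

setValidity("ModelParameters", function(object) {
  msg <- character()
  kn <- paste0("k", 1:7)
  if (length(object@rates) != 7L || !identical(names(object@rates), kn))
    msg <- c(msg, "rates must be a named numeric vector k1..k7")
  vals <- c(object@rates, object@receptorTotal, object@reporterTotal)
  if (any(!is.finite(vals)) || any(vals < 0))
    msg <- c(msg, "rate constants and totals must be nonnegative and finite")
  if (length(object@cellRadius) != 1L || !is.finite(object@cellRadius) ||
      object@cellRadius <= 0)
    msg <- c(msg, "cellRadius must be a positive finite scalar")
  if (length(msg)) msg else TRUE
})

#' LigandSpec: identity and tuning factors of an RTK ligand
#'
#' A ligand is characterized by two dimensionless fold-scalings of
#' dissociation rates: beta multiplies the ligand dissociation rate k7
#' (binding affinity) and gamma multiplies the ligand-bound dimer
#' dissociation rate k3 (dimerization affinity of ligand-bound receptors).
#' beta = gamma = 1 is the high-affinity (EGF) base case; low-affinity
#' ligands such as epiregulin are modeled with beta, gamma > 1.
#'
#' @slot name ligand name.
#' @slot beta dimensionless fold-scaling of k7 (> 0).
#' @slot gamma dimensionless fold-scaling of k3 (> 0).
#' @slot molecularWeight in g/mol.
#' @slot dose in ng/mL (>= 0).
#' @exportClass LigandSpec
setClass("LigandSpec",
  representation(
    name = "character",
    beta = "numeric",
    gamma = "numeric",
    molecularWeight = "numeric",
    dose = "numeric"
  )
)

setValidity("LigandSpec", function(object) {
  msg <- character()
  for (s in c("beta", "gamma", "molecularWeight")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a positive finite scalar", s))
  }
  if (length(object@dose) != 1L || !is.finite(object@dose) || object@dose < 0)
    msg <- c(msg, "dose must be a nonnegative finite scalar (ng/mL)")
  if (length(msg)) msg else TRUE
})

#' ReactionNetwork: species catalogue, reaction list and stoichiometry
#'
#' The declarative form of the activation network: a species table with
#' structural annotations (receptor count, ligand/reporter occupancy, dimer
#' and free-species flags), a reaction table (rate-constant name, statistical
#' multiplicity, one or two reactant indices) and the stoichiometry matrix
#' from which the mass-action right-hand side is generated. Free ligand is
#' clamped: its stoichiometry row is identically zero.
#'
#' @slot species data.frame, one row per species N1..N16.
#' @slot reactions data.frame, one row per elementary reaction.
#' @slot stoichiometry integer matrix, species x reactions.
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  representation(
    species = "data.frame",
    reactions = "data.frame",
    stoichiometry = "matrix"
  )
)

#' Trajectory: a solved timecourse of the activation network
#'
#' @slot times output grid (s), strictly increasing, starting at 0.
#' @slot states matrix (time x 16 species), molar, columns N1..N16.
#' @slot clearance percentage of reporter cleared from the cytosol at each
#'   output time (100 x bound/total).
#' @slot metadata list: parameters, ligand, solver settings.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    times = "numeric",
    states = "matrix",
    clearance = "numeric",
    metadata = "list"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@states) != length(object@times))
    msg <- c(msg, "states must have one row per time point")
  if (length(object@clearance) != length(object@times))
    msg <- c(msg, "clearance must align with times")
  if (length(msg)) msg else TRUE
})

#' EquilibriumResult: analytic pre-stimulus state of the network
#'
#' @slot N3o pre-stimulus receptor monomer concentration (M).
#' @slot N5o pre-stimulus ligand-free dimer concentration (M).
#' @slot state full 16-species concentration vector (M).
#' @slot residualNorm max |dN/dt| of the state under the ligand-free
#'   dynamics (M/s), a numerical fixed-point check.
#' @exportClass EquilibriumResult
setClass("EquilibriumResult",
  representation(
    N3o = "numeric",
    N5o = "numeric",
    state = "numeric",
    residualNorm = "numeric"
  )
)

#' RegimeLabel: kinetic classification of a clearance trajectory
#'
#' @slot label one of "biphasic-rising", "peak-plateau", "gradual-rising",
#'   "flat".
#' @slot diagnostics list with earlySlope, lateSlope, tHalf, overshootRatio
#'   and the threshold set used.
#' @exportClass RegimeLabel
setClass("RegimeLabel",
  representation(label = "character", diagnostics = "list")
)

#' FitResult: ligand scale factors recovered from clearance traces
#'
#' @slot betaHat,gammaHat recovered dissociation-rate scale factors.
#' @slot scaleHat optional amplitude scale (NA when not fitted).
#' @slot loss sum of squared residuals at the optimum.
#' @slot restarts data.frame of per-restart starting points, losses and
#'   convergence codes.
#' @slot convergence optim convergence code of the best restart.
#' @slot warnings character vector (e.g. non-identifiability).
#' @slot seed the seed used for the restart draws.
#' @exportClass FitResult
setClass("FitResult",
  representation(
    betaHat = "numeric",
    gammaHat = "numeric",
    scaleHat = "numeric",
    loss = "numeric",
    restarts = "data.frame",
    convergence = "numeric",
    warnings = "character",
    seed = "numeric"
  )
)
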