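# Parameters, ligands and unit conversions. Internal units are molar and
# seconds; ng/mL doses and molecule counts are converted at the boundary.

.AVOGADRO <- 6.02214076e23

#' Convert a per-cell molecule count to a molar concentration
#'
#' The cell is treated as a sphere of the given radius; the concentration is
#' count / (Avogadro x volume in liters). The default receptor load of
#' 250,000 molecules in a 10 um sphere gives ~9.91e-8 M.
#'
#' @param count molecule count (>= 0).
#' @param radius cell radius in micrometers (> 0).
#' @return concentration in molar.
#' @examples
#' moleculesToConcentration(250000, 10)
#' @export
moleculesToConcentration <- function(count, radius) {
  if (any(count < 0)) stop("count must be nonnegative")
  if (any(radius <= 0)) stop("radius must be positive")
  volumeL <- (4 / 3) * pi * (radius * 1e-6)^3 * 1e3  # m^3 -> L
  count / (.AVOGADRO * volumeL)
}

#' Convert a mass dose (ng/mL) to a molar concentration
#'
#' @param dose dose in ng/mL (>= 0); 1 ng/mL = 1e-6 g/L.
#' @param molecularWeight in g/mol (> 0).
#' @return concentration in molar.
#' @examples
#' doseToConcentration(100, 6222)
#' @export
doseToConcentration <- function(dose, molecularWeight) {
  if (any(dose < 0)) stop("dose must be nonnegative")
  if (any(molecularWeight <= 0)) stop("molecularWeight must be positive")
  dose * 1e-6 / molecularWeight
}

#' Construct the model parameter set
#'
#' Defaults are the package's base (EGF-like) calibration: literature-range
#' ligand binding (k1, k7; Kd = 1 nM) and reporter-ITAM binding (k2, k4;
#' Kd = 5 nM), the tight-binding ligand-free dimer dissociation rate
#' k6 = 5e-3 /s, and lumped dimerization constants (k5, k3) set so that a
#' saturating-dose response is biphasic: a sub-minute fast phase carried by
#' the pre-formed dimer pool followed by a tens-of-minutes
#' dimerization-limited rise. See the package vignette for the rationale
#' behind each value.
#'
#' @param k1 ligand association, 1/M/s.
#' @param k2 reporter association, 1/M/s.
#' @param k3 ligand-bound dimer dissociation, 1/s (gamma-scaled).
#' @param k4 reporter dissociation, 1/s.
#' @param k5 dimerization forward rate, 1/M/s.
#' @param k6 ligand-free dimer dissociation, 1/s.
#' @param k7 ligand dissociation, 1/s (beta-scaled).
#' @param receptorsPerCell receptor copy number per cell.
#' @param cellRadius cell radius, micrometers.
#' @param receptorTotal total receptor concentration (M); derived from
#'   `receptorsPerCell` and `cellRadius` when NULL.
#' @param reporterTotal total reporter concentration (M); equal to
#'   `receptorTotal` (1:1 molar ratio) when NULL.
#' @return a [ModelParameters-class] object.
#' @examples
#' p <- modelParameters()
#' receptorTotal(p)
#' @export
modelParameters <- function(k1 = 1e7, k2 = 1e7, k3 = 1e-4, k4 = 5e-2,
                            k5 = 5e3, k6 = 5e-3, k7 = 1e-2,
                            receptorsPerCell = 250000, cellRadius = 10,
                            receptorTotal = NULL, reporterTotal = NULL) {
  if (is.null(receptorTotal))
    receptorTotal <- moleculesToConcentration(receptorsPerCell, cellRadius)
  if (is.null(reporterTotal))
    reporterTotal <- receptorTotal
  new("ModelParameters",
      rates = c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
                k7 = k7),
      receptorTotal = receptorTotal, reporterTotal = reporterTotal,
      receptorsPerCell = receptorsPerCell, cellRadius = cellRadius)
}

#' @rdname modelParameters
#' @param params a ModelParameters object.
#' @export
rateConstants <- function(params) params@rates

#' @rdname modelParameters
#' @export
receptorTotal <- function(params) params@receptorTotal

#' @rdname modelParameters
#' @export
reporterTotal <- function(params) params@reporterTotal

#' Return a copy of a parameter set with some fields replaced
#'
#' @param params a [ModelParameters-class].
#' @param ... any of k1..k7, receptorTotal, reporterTotal.
#' @return a new ModelParameters object.
#' @examples
#' p2 <- updateParameters(modelParameters(), k6 = 1e-2)
#' @export
updateParameters <- function(params, ...) {
  stopifnot(is(params, "ModelParameters"))
  dots <- list(...)
  kn <- paste0("k", 1:7)
  for (nm in names(dots)) {
    if (nm %in% kn) {
      params@rates[nm] <- dots[[nm]]
    } else if (nm %in% c("receptorTotal", "reporterTotal")) {
      slot(params, nm) <- dots[[nm]]
    } else stop("unknown parameter field: ", nm)
  }
  validObject(params)
  params
}

#' Construct a ligand specification
#'
#' beta multiplies the ligand dissociation rate k7 (lower binding affinity
#' for beta > 1); gamma multiplies the ligand-bound dimer dissociation rate
#' k3 (lower dimerization affinity for gamma > 1). beta = gamma = 1 is the
#' EGF base case.
#'
#' @param name ligand name.
#' @param dose dose in ng/mL.
#' @param beta,gamma dimensionless dissociation-rate scale factors (> 0).
#' @param molecularWeight g/mol; the default 6222 (EGF-like) is also used
#'   for EREG/EPGN-like ligands so that dose comparisons stay in ng/mL.
#' @return a [LigandSpec-class] object.
#' @examples
#' ligandSpec("EGF", dose = 20)
#' ligandSpec("EREG", dose = 20, beta = 50, gamma = 100)
#' @export
ligandSpec <- function(name = "EGF", dose = 0, beta = 1, gamma = 1,
                       molecularWeight = 6222) {
  new("LigandSpec", name = name, beta = beta, gamma = gamma,
      molecularWeight = molecularWeight, dose = dose)
}

#' Molar concentration of a ligand at its configured dose
#'
#' @param ligand a [LigandSpec-class].
#' @return concentration in molar.
#' @export
ligandConcentration <- function(ligand) {
  stopifnot(is(ligand, "LigandSpec"))
  doseToConcentration(ligand@dose, ligand@molecularWeight)
}

#' Apply ligand-specific scaling to the rate constants
#'
#' Returns a copy of `params` with k7 <- beta * k7 and k3 <- gamma * k3;
#' all other constants are untouched. Scaling composes multiplicatively and
#' beta = gamma = 1 returns the base rates unchanged (bit-identical).
#'
#' @param params a [ModelParameters-class].
#' @param ligand a [LigandSpec-class] (or NULL for no scaling).
#' @return a new ModelParameters object.
#' @examples
#' p <- modelParameters()
#' rateConstants(applyLigandScaling(p, ligandSpec("EREG", beta = 50, gamma = 100)))
#' @export
applyLigandScaling <- function(params, ligand) {
  stopifnot(is(params, "ModelParameters"))
  if (is.null(ligand)) return(params)
  stopifnot(is(ligand, "LigandSpec"))
  if (ligand@beta <= 0 || ligand@gamma <= 0)
    stop("beta and gamma must be positive")
  if (ligand@beta != 1) params@rates["k7"] <- ligand@beta * params@rates["k7"]
  if (ligand@gamma != 1) params@rates["k3"] <- ligand@gamma * params@rates["k3"]
  params
}

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters\n")
  k <- object@rates
  cat(sprintf("  %s = %.4g %s\n", names(k), k,
              ifelse(names(k) %in% c("k1", "k2", "k5"), "1/M/s", "1/s")),
      sep = "")
  cat(sprintf("  receptor total = %.4g M (%g molecules, r = %g um)\n",
              object@receptorTotal, object@receptorsPerCell,
              object@cellRadius))
  cat(sprintf("  reporter total = %.4g M\n", object@reporterTotal))
})

setMethod("show", "LigandSpec", function(object) {
  cat(sprintf("LigandSpec '%s': dose = %g ng/mL (%.3g M), beta = %g, gamma = %g, MW = %g g/mol\n",
              object@name, object@dose, ligandConcentration(object),
              object@beta, object@gamma, object@molecularWeight))
})

# ---- configuration files ----------------------------------------------------

#' Read or write a model/ligand configuration file
#'
#' The configuration is a YAML or JSON document (chosen by file extension)
#' with two blocks: `parameters` (k1..k7, receptorsPerCell, cellRadius,
#' optional receptorTotal/reporterTotal; units are fixed: 1/M/s for
#' second-order constants, 1/s for first-order, molar for totals, um for the
#' radius) and `ligand` (name, dose_ng_per_mL, beta, gamma,
#' molecularWeight_g_per_mol). Unknown fields are rejected.
#'
#' @param path file path ending in .yaml, .yml or .json.
#' @return `readModelConfig`: a list with elements `params`
#'   ([ModelParameters-class]) and `ligand` ([LigandSpec-class]).
#' @export
readModelConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config file must be .yaml, .yml or .json")
  okP <- c(paste0("k", 1:7), "receptorsPerCell", "cellRadius",
           "receptorTotal", "reporterTotal")
  okL <- c("name", "dose_ng_per_mL", "beta", "gamma",
           "molecularWeight_g_per_mol")
  if (!all(names(cfg) %in% c("parameters", "ligand")))
    stop("config must contain only 'parameters' and 'ligand' blocks")
  pc <- cfg$parameters %||% list()
  lc <- cfg$ligand %||% list()
  if (length(bad <- setdiff(names(pc), okP)))
    stop("unknown parameter fields: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(names(lc), okL)))
    stop("unknown ligand fields: ", paste(bad, collapse = ", "))
  params <- do.call(modelParameters, pc)
  ligand <- ligandSpec(
    name = lc$name %||% "EGF",
    dose = lc$dose_ng_per_mL %||% 0,
    beta = lc$beta %||% 1,
    gamma = lc$gamma %||% 1,
    molecularWeight = lc$molecularWeight_g_per_mol %||% 6222
  )
  list(params = params, ligand = ligand)
}

#' @rdname readModelConfig
#' @param params a [ModelParameters-class].
#' @param ligand a [LigandSpec-class].
#' @export
writeModelConfig <- function(params, ligand, path) {
  cfg <- list(
    parameters = c(as.list(params@rates),
                   list(receptorsPerCell = params@receptorsPerCell,
                        cellRadius = params@cellRadius,
                        receptorTotal = params@receptorTotal,
                        reporterTotal = params@reporterTotal)),
    ligand = list(name = ligand@name, dose_ng_per_mL = ligand@dose,
                  beta = ligand@beta, gamma = ligand@gamma,
                  molecularWeight_g_per_mol = ligand@molecularWeight)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else stop("config file must be .yaml, .yml or .json")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
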