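# Trajectory serialization: tidy delimited text plus a JSON metadata sidecar.

#' Write or read a trajectory as tidy delimited text
#'
#' The table has one row per output time with columns `time_s`, the 16
#' species concentrations (molar, N1..N16) and `clearance_pct`. Solver and
#' ligand metadata go to a JSON sidecar `<path>.json`. Identical inputs at
#' fixed solver settings serialize bit-identically.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  df <- data.frame(time_s = trajectory@times,
                   trajectory@states,
                   clearance_pct = trajectory@clearance,
                   check.names = FALSE)
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- trajectory@metadata
  lig <- md$ligand
  side <- list(
    solver = md$solver, rtol = md$rtol, atol = md$atol, dt = md$dt,
    duration = md$duration, outputStep = md$outputStep,
    conservationDrift = md$conservationDrift,
    ligand = if (!is.null(lig)) list(
      name = lig@name, dose_ng_per_mL = lig@dose, beta = lig@beta,
      gamma = lig@gamma, molecularWeight_g_per_mol = lig@molecularWeight),
    rates = if (!is.null(md$params)) as.list(md$params@rates),
    receptorTotal = if (!is.null(md$params)) md$params@receptorTotal,
    reporterTotal = if (!is.null(md$params)) md$params@reporterTotal)
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrajectory
#' @return `readTrajectory`: a [Trajectory-class] (metadata restored from
#'   the sidecar as a plain list).
#' @export
readTrajectory <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  labels <- paste0("N", 1:16)
  stopifnot(all(c("time_s", labels, "clearance_pct") %in% names(df)))
  side <- paste0(path, ".json")
  md <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
        else list()
  new("Trajectory", times = df$time_s,
      states = as.matrix(df[, labels]),
      clearance = df$clearance_pct, metadata = md)
}

#' Plot the clearance readout of one or more trajectories
#'
#' @param ... [Trajectory-class] objects (named arguments become legend
#'   labels).
#' @param col line colors.
#' @export
plotTrajectory <- function(..., col = NULL) {
  trs <- list(...)
  if (is.null(col)) col <- seq_along(trs)
  ylim <- range(0, vapply(trs, function(tr) max(tr@clearance), 0))
  plot(NA, xlim = c(0, max(vapply(trs, function(tr) max(tr@times), 0))) / 60,
       ylim = ylim, xlab = "time (min)", ylab = "cytosolic clearance (%)")
  for (i in seq_along(trs))
    lines(trs[[i]]@times / 60, trs[[i]]@clearance, col = col[i], lwd = 2)
  if (!is.null(names(trs)) && any(nzchar(names(trs))))
    legend("bottomright", legend = names(trs), col = col, lwd = 2, bty = "n")
  invisible(NULL)
}
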