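# CellTraceSet: per-cell intensity timeseries as a SummarizedExperiment
# (rows = cells, columns = frames). Assays hold the channels ("cytosolic",
# optionally "nuclear", plus derived "activity" and generator ground truth);
# rowData carries per-cell annotations (experiment, expression proxies);
# colData carries the shared time grid.

#' CellTraceSet: per-cell intensity timeseries
#'
#' Extends SummarizedExperiment with rows as cells and columns as frames.
#' All cells of an experiment share the time grid stored in `colData`
#' (columns `frame`, `time_s`). `metadata()` holds `stimulationFrame` (the
#' first post-stimulus frame; all earlier frames are pre-stimulus baseline)
#' and, for synthetic data, the generator ground truth.
#'
#' @exportClass CellTraceSet
setClass("CellTraceSet", contains = "SummarizedExperiment")

setValidity("CellTraceSet", function(object) {
  msg <- character()
  if (!"cytosolic" %in% assayNames(object))
    msg <- c(msg, "assay 'cytosolic' is required")
  if (!all(c("frame", "time_s") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'frame' and 'time_s'")
  sf <- metadata(object)$stimulationFrame
  if (!is.null(sf) && (sf < 2 || sf > ncol(object)))
    msg <- c(msg, "stimulationFrame must leave at least one pre-stimulus frame")
  if (length(msg)) msg else TRUE
})

#' Construct a CellTraceSet from channel matrices
#'
#' @param cytosolic cells x frames matrix of cytosolic reporter intensity.
#' @param times frame times in seconds (length = ncol).
#' @param nuclear optional cells x frames nuclear-channel matrix.
#' @param stimulationFrame index of the first post-stimulus frame (>= 2).
#' @param experiment per-cell experiment identifier (recycled).
#' @param receptorExpr,reporterExpr optional per-cell pre-stimulus
#'   expression proxies.
#' @param ... further assays (cells x frames matrices).
#' @return a [CellTraceSet-class].
#' @export
CellTraceSet <- function(cytosolic, times, nuclear = NULL,
                         stimulationFrame = 2L, experiment = "exp1",
                         receptorExpr = NULL, reporterExpr = NULL, ...) {
  cytosolic <- as.matrix(cytosolic)
  nCell <- nrow(cytosolic); nFrame <- ncol(cytosolic)
  stopifnot(length(times) == nFrame)
  assays <- c(list(cytosolic = cytosolic),
              if (!is.null(nuclear)) list(nuclear = as.matrix(nuclear)),
              list(...))
  rd <- S4Vectors::DataFrame(
    cell = if (is.null(rownames(cytosolic)))
      sprintf("cell%03d", seq_len(nCell)) else rownames(cytosolic),
    experiment = rep_len(experiment, nCell))
  if (!is.null(receptorExpr)) rd$receptorExpr <- receptorExpr
  if (!is.null(reporterExpr)) rd$reporterExpr <- reporterExpr
  cd <- S4Vectors::DataFrame(frame = seq_len(nFrame), time_s = times)
  se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd)
  rownames(se) <- rd$cell
  obj <- new("CellTraceSet", se)
  metadata(obj)$stimulationFrame <- as.integer(stimulationFrame)
  validObject(obj)
  obj
}

#' @rdname CellTraceSet
#' @param x a CellTraceSet.
#' @export
cytosolic <- function(x) assay(x, "cytosolic")

#' @rdname CellTraceSet
#' @export
nuclearIntensity <- function(x) {
  if (!"nuclear" %in% assayNames(x)) stop("no nuclear channel present")
  assay(x, "nuclear")
}

#' @rdname CellTraceSet
#' @export
traceTimes <- function(x) colData(x)$time_s

#' @rdname CellTraceSet
#' @export
stimulationFrame <- function(x) metadata(x)$stimulationFrame %||% 2L

#' Read or write per-cell traces as tidy delimited text
#'
#' The tidy format has one row per (experiment, cell, frame) with columns
#' `experiment`, `cell`, `frame`, `time_s`, `cytosolic` and optionally
#' `nuclear`, `receptor_expr`, `reporter_expr`. The stimulation frame is
#' stored in a JSON sidecar `<path>.json` (written/read automatically).
#'
#' @param path a tab-separated file.
#' @return `readCellTraces`: a [CellTraceSet-class].
#' @export
readCellTraces <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("experiment", "cell", "frame", "time_s", "cytosolic")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[order(df$cell, df$frame), ]
  cells <- unique(df$cell)
  frames <- sort(unique(df$frame))
  shape <- function(col)
    matrix(df[[col]][order(match(df$cell, cells), df$frame)],
           nrow = length(cells), ncol = length(frames), byrow = TRUE,
           dimnames = list(cells, NULL))
  times <- df$time_s[match(frames, df$frame)]
  firstRow <- df[match(cells, df$cell), ]
  side <- paste0(path, ".json")
  sf <- if (file.exists(side))
    jsonlite::read_json(side)$stimulationFrame else 2L
  CellTraceSet(
    cytosolic = shape("cytosolic"), times = times,
    nuclear = if ("nuclear" %in% names(df)) shape("nuclear"),
    stimulationFrame = as.integer(sf),
    experiment = firstRow$experiment,
    receptorExpr = if ("receptor_expr" %in% names(df)) firstRow$receptor_expr,
    reporterExpr = if ("reporter_expr" %in% names(df)) firstRow$reporter_expr)
}

#' @rdname readCellTraces
#' @param traces a [CellTraceSet-class].
#' @export
writeCellTraces <- function(traces, path) {
  stopifnot(is(traces, "CellTraceSet"))
  rd <- rowData(traces)
  cd <- colData(traces)
  nC <- nrow(traces); nF <- ncol(traces)
  df <- data.frame(
    experiment = rep(rd$experiment, each = nF),
    cell = rep(rownames(traces), each = nF),
    frame = rep(cd$frame, times = nC),
    time_s = rep(cd$time_s, times = nC),
    cytosolic = as.vector(t(cytosolic(traces))))
  if ("nuclear" %in% assayNames(traces))
    df$nuclear <- as.vector(t(assay(traces, "nuclear")))
  if ("receptorExpr" %in% colnames(rd))
    df$receptor_expr <- rep(rd$receptorExpr, each = nF)
  if ("reporterExpr" %in% colnames(rd))
    df$reporter_expr <- rep(rd$reporterExpr, each = nF)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(stimulationFrame = stimulationFrame(traces)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

setMethod("show", "CellTraceSet", function(object) {
  cat(sprintf("CellTraceSet: %d cells x %d frames (%d experiment(s)), stimulation at frame %d\n",
              nrow(object), ncol(object),
              length(unique(rowData(object)$experiment)),
              stimulationFrame(object)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})
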