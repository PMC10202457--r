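# Quantification of biosensor and KTR trajectories from per-cell intensity
# tables: percent-cleared activity, frame-wide artifact repair, min-max
# normalization, time to half-max, KTR ratios, hierarchical replicate
# aggregation and expression-ratio ordering.

#' Percent-cleared activity from cytosolic intensities
#'
#' activity(t) = -100 x (Icyt(t) / Icyt0 - 1), where Icyt0 is the mean
#' cytosolic intensity over the pre-stimulus frames (all frames strictly
#' before the stimulation frame). A drop of cytosolic intensity to 60% of
#' baseline is an activity of 40%; brightening gives negative values.
#'
#' @param traces a [CellTraceSet-class].
#' @return the input with an `activity` assay added and per-cell baselines
#'   in `rowData(...)$baseline`.
#' @export
clearanceActivity <- function(traces) {
  stopifnot(is(traces, "CellTraceSet"))
  sf <- stimulationFrame(traces)
  if (sf < 2) stop("at least one pre-stimulus frame is required")
  I <- cytosolic(traces)
  base <- rowMeans(I[, seq_len(sf - 1L), drop = FALSE])
  if (any(base <= 0)) stop("nonpositive pre-stimulus baseline")
  act <- -100 * (sweep(I, 1, base, "/") - 1)
  assay(traces, "activity") <- act
  rowData(traces)$baseline <- base
  traces
}

#' Detect and repair frame-wide intensity artifacts
#'
#' Occasional aberrant frames (abnormally dark or bright acquisitions)
#' shift the measured intensity of every cell at once. A frame is flagged
#' when the median across cells of the signed relative intensity change
#' from the previous (already repaired) frame exceeds `threshold` in
#' magnitude AND at least `agreement` of cells change in the same
#' direction. Flagged frames are replaced, for every cell, by that cell's
#' previous-frame value (carried forward through runs of flagged frames);
#' single-cell spikes are never frame-wide and are left untouched.
#'
#' @param traces a [CellTraceSet-class] (>= 2 frames).
#' @param threshold median |relative change| required to flag (default 0.30).
#' @param agreement minimum fraction of cells changing in the common
#'   direction (default 0.8).
#' @return the input with the `cytosolic` (and, when present, `nuclear`)
#'   assay repaired and the flagged frame indices in
#'   `metadata(...)$replacedFrames`.
#' @export
repairAberrantFrames <- function(traces, threshold = 0.30, agreement = 0.80) {
  stopifnot(is(traces, "CellTraceSet"))
  I <- cytosolic(traces)
  if (ncol(I) < 2L) stop("at least two frames are required")
  flagged <- integer(0)
  for (f in 2:ncol(I)) {
    prev <- I[, f - 1L]
    rel <- (I[, f] - prev) / prev
    med <- median(rel)
    dirFrac <- max(mean(rel > 0), mean(rel < 0))
    if (abs(med) > threshold && dirFrac >= agreement) {
      flagged <- c(flagged, f)
      I[, f] <- prev  # placeholder: previous time point, per cell
      if ("nuclear" %in% assayNames(traces))
        assay(traces, "nuclear")[, f] <- assay(traces, "nuclear")[, f - 1L]
    }
  }
  if (1L %in% flagged)
    stop("first frame cannot be repaired")  # unreachable: loop starts at 2
  assay(traces, "cytosolic") <- I
  metadata(traces)$replacedFrames <- flagged
  traces
}

#' Min-max normalize a trace to [0, 1]
#'
#' (x - min) / (max - min); idempotent on already-normalized traces and
#' order-preserving. Errors on constant traces.
#'
#' @param x numeric vector.
#' @return normalized vector in [0, 1].
#' @export
minmaxNormalize <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("constant trace cannot be min-max normalized")
  (x - r[1]) / (r[2] - r[1])
}

#' Time to half-maximal response
#'
#' First time the trace crosses 50% of its maximum, linearly interpolated
#' between frames. If the trace starts at or above half-maximum the first
#' frame time is returned with `degenerate = TRUE`.
#'
#' @param trace numeric response values.
#' @param times frame times (s), same length.
#' @return list with `time` (s), `halfMax`, and `degenerate` flag.
#' @examples
#' timeToHalfMax(c(0, 25, 50, 75, 100), 0:4 * 60)$time  # 120 s
#' @export
timeToHalfMax <- function(trace, times) {
  stopifnot(length(trace) == length(times), length(trace) >= 2L)
  m <- max(trace)
  if (m <= 0) stop("trace never reaches a positive maximum")
  h <- m / 2
  if (trace[1] >= h) {
    warning("trace starts at or above half-maximum; returning first frame time")
    return(list(time = times[1], halfMax = h, degenerate = TRUE))
  }
  i <- which(trace >= h)[1]
  t0 <- times[i - 1L]; t1 <- times[i]
  y0 <- trace[i - 1L]; y1 <- trace[i]
  list(time = t0 + (h - y0) / (y1 - y0) * (t1 - t0), halfMax = h,
       degenerate = FALSE)
}

#' Kinase-translocation-reporter activity ratio
#'
#' Elementwise cytosolic / nuclear intensity ratio per cell and frame;
#' rises when the kinase is active and the reporter leaves the nucleus.
#'
#' @param traces a [CellTraceSet-class] with a nuclear channel.
#' @return the input with a `ktrRatio` assay added.
#' @export
ktrActivity <- function(traces) {
  stopifnot(is(traces, "CellTraceSet"))
  nuc <- nuclearIntensity(traces)
  if (any(nuc <= 0)) stop("nonpositive nuclear intensities")
  assay(traces, "ktrRatio") <- cytosolic(traces) / nuc
  traces
}

#' Membrane enrichment from a line profile
#'
#' The membrane intensity is the maximum of a fluorescence line scan drawn
#' perpendicular to the membrane; the peak position is returned alongside.
#'
#' @param profile numeric intensity values along the line.
#' @param positions optional coordinates (defaults to 1..n).
#' @return list with `peak` (intensity) and `position`.
#' @export
membraneEnrichment <- function(profile, positions = seq_along(profile)) {
  if (!length(profile)) stop("empty profile")
  i <- which.max(profile)
  list(peak = profile[i], position = positions[i])
}

#' Aggregate activity traces across experiments
#'
#' Hierarchical aggregation: the per-experiment mean trace over cells is
#' computed first, then the grand mean and sample SD are taken across the
#' experiment means (never across pooled cells), so unbalanced designs do
#' not overweight large experiments.
#'
#' @param traces a [CellTraceSet-class] with an `activity` assay (see
#'   [clearanceActivity()]), or any assay named by `assayName`.
#' @param assayName assay to aggregate (default "activity").
#' @return data.frame with columns time_s, mean, sd, nExperiments, plus an
#'   attribute `experimentMeans` (experiments x frames matrix).
#' @export
aggregateReplicates <- function(traces, assayName = "activity") {
  stopifnot(is(traces, "CellTraceSet"))
  if (!assayName %in% assayNames(traces))
    stop("assay '", assayName, "' not present; run clearanceActivity() first")
  A <- assay(traces, assayName)
  exper <- as.character(rowData(traces)$experiment)
  if (!length(exper) || any(!nzchar(exper))) stop("empty experiment labels")
  groups <- split(seq_len(nrow(A)), exper)
  em <- t(vapply(groups, function(ix) colMeans(A[ix, , drop = FALSE]),
                 numeric(ncol(A))))
  out <- data.frame(
    time_s = traceTimes(traces),
    mean = colMeans(em),
    sd = if (nrow(em) > 1L) apply(em, 2, sd) else rep(0, ncol(em)),
    nExperiments = nrow(em))
  attr(out, "experimentMeans") <- em
  out
}

#' Order cells by receptor:reporter expression ratio
#'
#' Attaches the ratio of the pre-stimulus expression proxies and returns
#' the set with rows (cells) sorted by increasing ratio, the layout used
#' for response heatmaps.
#'
#' @param traces a [CellTraceSet-class] with `receptorExpr` and
#'   `reporterExpr` in `rowData`.
#' @return the reordered [CellTraceSet-class] with `rowData(...)$exprRatio`.
#' @export
sortByExpressionRatio <- function(traces) {
  stopifnot(is(traces, "CellTraceSet"))
  rd <- rowData(traces)
  if (!all(c("receptorExpr", "reporterExpr") %in% colnames(rd)))
    stop("expression proxies are required")
  if (any(rd$reporterExpr <= 0)) stop("nonpositive reporter expression")
  ratio <- rd$receptorExpr / rd$reporterExpr
  rowData(traces)$exprRatio <- ratio
  traces[order(ratio), ]
}
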