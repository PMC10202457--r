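# Quantification operations on small hand-built trace sets.

makeTraces <- function(I, times = (seq_len(ncol(I)) - 1) * 30,
                       stimulationFrame = 3L, ...) {
  CellTraceSet(cytosolic = I, times = times,
               stimulationFrame = stimulationFrame, ...)
}

test_that("clearance activity implements the baseline-normalized drop", {
  # two pre-stimulus frames at 1000, then steps of known fractions
  I <- rbind(c(1000, 1000, 600, 1200, 1000),
             c(500, 500, 500, 500, 500))
  cts <- clearanceActivity(makeTraces(I))
  act <- assay(cts, "activity")
  expect_equal(act[1, ], c(0, 0, 40, -20, 0))   # 0.6x -> 40%, 1.2x -> -20%
  expect_equal(act[2, ], rep(0, 5))             # constant trace -> 0
  expect_equal(unname(rowData(cts)$baseline), c(1000, 500))
  # pre-stimulus activity averages to zero by construction
  expect_equal(mean(act[, 1:2]), 0)
  bad <- makeTraces(rbind(c(0, 0, 1, 1, 1)))
  expect_error(clearanceActivity(bad), "baseline")
})

test_that("frame-wide artifacts are detected, repaired locally, and single-cell spikes ignored", {
  set.seed(3)
  n <- 20; f <- 30
  clean <- matrix(1000 * exp(0.02 * rnorm(n * f)), n, f)
  # clean data: nothing flagged, values untouched
  r0 <- repairAberrantFrames(makeTraces(clean))
  expect_length(metadata(r0)$replacedFrames, 0)
  expect_identical(unname(cytosolic(r0)), clean)
  # one frame multiplied by 3 across all cells
  dirty <- clean
  dirty[, 12] <- 3 * dirty[, 12]
  r1 <- repairAberrantFrames(makeTraces(dirty))
  expect_equal(metadata(r1)$replacedFrames, 12L)
  expect_equal(unname(cytosolic(r1)[, 12]), dirty[, 11])  # previous-frame placeholder
  # repair touches only the flagged frame
  expect_identical(unname(cytosolic(r1)[, -12]), dirty[, -12])
  # a single-cell spike is not frame-wide and is left alone
  spike <- clean
  spike[4, 7] <- 10 * spike[4, 7]
  r2 <- repairAberrantFrames(makeTraces(spike))
  expect_length(metadata(r2)$replacedFrames, 0)
  expect_identical(unname(cytosolic(r2)), spike)
  # consecutive artifact frames are carried forward from the last good frame
  run <- clean
  run[, 20] <- 3 * run[, 20]; run[, 21] <- 3 * run[, 21]
  r3 <- repairAberrantFrames(makeTraces(run))
  expect_equal(metadata(r3)$replacedFrames, c(20L, 21L))
  expect_equal(unname(cytosolic(r3)[, 21]), run[, 19])
})

test_that("min-max normalization is exact, idempotent and order-preserving", {
  expect_equal(minmaxNormalize(c(0, 50, 100)), c(0, 0.5, 1))
  expect_equal(minmaxNormalize(c(-10, 0, 30)), c(0, 0.25, 1))
  x <- c(3, -2, 7, 7, 0)
  nx <- minmaxNormalize(x)
  expect_identical(order(nx), order(x))
  expect_equal(minmaxNormalize(nx), nx)
  expect_error(minmaxNormalize(rep(2, 5)), "constant")
})

test_that("time to half-max interpolates the first crossing", {
  expect_equal(timeToHalfMax(c(0, 25, 50, 75, 100), 0:4 * 60)$time, 120)
  expect_equal(timeToHalfMax(c(0, 100, 100), 0:2 * 60)$time, 30)
  # non-monotone trace: first crossing counts
  expect_equal(timeToHalfMax(c(0, 80, 20, 100), 0:3)$time, 0.625)
  expect_error(timeToHalfMax(c(-1, -2, -3), 0:2), "positive maximum")
  w <- expect_warning(timeToHalfMax(c(60, 80, 100), 0:2), "half-maximum")
})

test_that("KTR ratio divides cytosolic by nuclear per frame", {
  cyt <- rbind(c(10, 20, 30), c(5, 5, 5))
  nuc <- rbind(c(10, 10, 10), c(5, 5, 5))
  cts <- CellTraceSet(cyt, times = 0:2 * 30, nuclear = nuc,
                      stimulationFrame = 2L)
  r <- assay(ktrActivity(cts), "ktrRatio")
  expect_equal(r[1, ], c(1, 2, 3))
  expect_equal(r[2, ], c(1, 1, 1))
  noNuc <- CellTraceSet(cyt, times = 0:2 * 30, stimulationFrame = 2L)
  expect_error(ktrActivity(noNuc), "nuclear")
})

test_that("membrane enrichment returns the profile maximum and position", {
  expect_equal(membraneEnrichment(rep(7, 11))$peak, 7)
  prof <- generateLineProfile(membranePosition = 40, amplitude = 50,
                              width = 3, baseline = 100, noiseSD = 0)
  me <- membraneEnrichment(prof)
  expect_equal(me$position, 40)
  expect_equal(me$peak, 150, tolerance = 1e-12)
  # two bumps: apical > lateral ordering is recovered
  two <- generateLineProfile(membranePosition = c(25, 75),
                             amplitude = c(80, 30), width = 2)
  expect_equal(membraneEnrichment(two)$position, 25)
  expect_error(membraneEnrichment(numeric(0)), "empty")
})

test_that("replicate aggregation is hierarchical, not pooled", {
  # 2 experiments with constant activities 10% and 30%: mean 20, SD 14.14
  I <- rbind(900, 900, 900, 700)  # baselines 1000 -> activities 10,10,10,30
  I <- cbind(matrix(1000, 4, 2), matrix(I, 4, 3))
  cts <- CellTraceSet(I, times = 0:4 * 30, stimulationFrame = 3L,
                      experiment = c("e1", "e1", "e1", "e2"))
  agg <- aggregateReplicates(clearanceActivity(cts))
  expect_equal(agg$mean[4], 20)
  expect_equal(agg$sd[4], sqrt(2) * 10, tolerance = 1e-12)
  expect_equal(agg$nExperiments[1], 2)
  # pooled SD over cells would differ from the hierarchical value
  pooled <- sd(c(10, 10, 10, 30))
  expect_false(isTRUE(all.equal(pooled, sqrt(2) * 10)))
  # single experiment: SD identically zero
  one <- CellTraceSet(I[1:3, ], times = 0:4 * 30, stimulationFrame = 3L)
  expect_true(all(aggregateReplicates(clearanceActivity(one))$sd == 0))
  # invariance to cell order
  perm <- c(4, 2, 3, 1)
  cts2 <- CellTraceSet(I[perm, ], times = 0:4 * 30, stimulationFrame = 3L,
                       experiment = c("e2", "e1", "e1", "e1"))
  agg2 <- aggregateReplicates(clearanceActivity(cts2))
  expect_equal(agg2$mean, agg$mean)
  expect_equal(agg2$sd, agg$sd)
})

test_that("cells sort by receptor:reporter expression ratio", {
  I <- matrix(1000, 4, 3)
  cts <- CellTraceSet(I, times = 0:2 * 30, stimulationFrame = 2L,
                      receptorExpr = c(4, 1, 3, 2),
                      reporterExpr = c(1, 1, 1, 1))
  srt <- sortByExpressionRatio(cts)
  expect_equal(unname(rowData(srt)$receptorExpr), 1:4)
  expect_equal(unname(rowData(srt)$exprRatio), 1:4)
  # already sorted input is unchanged; reverse input is reversed
  expect_equal(rownames(sortByExpressionRatio(srt)), rownames(srt))
  bad <- CellTraceSet(I, times = 0:2 * 30, stimulationFrame = 2L,
                      receptorExpr = c(1, 1, 1, 1),
                      reporterExpr = c(1, 0, 1, 1))
  expect_error(sortByExpressionRatio(bad), "reporter expression")
})

test_that("trace tables round-trip through tidy delimited text", {
  set.seed(5)
  I <- matrix(1000 * exp(0.05 * rnorm(12)), 3, 4)
  nuc <- matrix(500, 3, 4)
  cts <- CellTraceSet(I, times = 0:3 * 30, nuclear = nuc,
                      stimulationFrame = 2L, experiment = "expA",
                      receptorExpr = c(1, 2, 3), reporterExpr = c(2, 2, 2))
  f <- file.path(tempdir(), "traces.tsv")
  writeCellTraces(cts, f)
  back <- readCellTraces(f)
  expect_equal(unname(cytosolic(back)), unname(cytosolic(cts)),
               tolerance = 1e-12)
  expect_equal(unname(assay(back, "nuclear")), unname(nuc))
  expect_equal(stimulationFrame(back), 2L)
  expect_equal(unname(rowData(back)$receptorExpr), c(1, 2, 3))
  expect_equal(traceTimes(back), 0:3 * 30)
})
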