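test_that("zero dose gives an identically flat clearance trace", {
  tr <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 0),
                           duration = 600)
  expect_true(all(abs(clearance(tr)) < 1e-8))
  expect_equal(classifyKinetics(tr, horizon = 600)@label, "flat")
})

test_that("clearance readout is the bound-reporter fraction", {
  Zt <- reporterTotal(baseParams)
  pre <- equilibriumState(analyticPrestimulusState(baseParams, baseNet))
  expect_equal(clearanceFromState(pre, Ztotal = Zt), 0)
  allBound <- numeric(16)                 # no free reporter left
  expect_equal(clearanceFromState(allBound, Ztotal = Zt), 100)
  s <- numeric(16); s[2] <- 0.6 * Zt
  expect_equal(clearanceFromState(s, Ztotal = Zt), 40)
  expect_error(clearanceFromState(s, Ztotal = 0), "positive")
})

test_that("trajectories conserve totals and start from the fixed point", {
  tr <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 20))
  expect_lt(tr@metadata$conservationDrift, 1e-6)
  expect_equal(clearance(tr)[1], 0, tolerance = 1e-10)
  # clearance stays within [0, 100]
  expect_true(all(clearance(tr) >= 0 & clearance(tr) <= 100))
  # saturating-dose base case: fast phase then continued slow rise
  trS <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 5000))
  cc <- clearance(trS); tt <- timePoints(trS)
  expect_true(all(diff(cc) > -1e-6))                     # monotone
  expect_gt(approx(tt, cc, 60)$y, 10)                    # fast phase
  expect_gt(tail(cc, 1), 1.3 * approx(tt, cc, 300)$y)    # slow rise goes on
  expect_equal(classifyKinetics(trS)@label, "biphasic-rising")
})

test_that("identical configurations give bit-identical trajectories", {
  a <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 20),
                          duration = 600)
  b <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 20),
                          duration = 600)
  expect_identical(speciesStates(a), speciesStates(b))
  expect_identical(clearance(a), clearance(b))
})

test_that("adaptive solver agrees with the fixed-step RK4 reference", {
  # short-horizon check at a moderately stiff setting; the acceptance
  # suite runs the full-horizon panels
  lig <- ligandSpec("g100", dose = 20, gamma = 100)
  ada <- simulateTimecourse(baseParams, lig, duration = 120)
  ref <- rk4Reference(baseParams, lig, duration = 120)
  relDiff <- abs(clearance(ada) - clearance(ref)) /
    pmax(abs(clearance(ref)), 1e-8)
  expect_lt(max(relDiff[-1]), 1e-4)
})

test_that("kinetic regimes are classified by their stated rules", {
  tt <- seq(0, 1800, by = 5)
  flat <- syntheticTrajectory(tt, rep(0, length(tt)))
  expect_equal(classifyKinetics(flat)@label, "flat")
  # early transient maximum decaying to a plateau
  peak <- syntheticTrajectory(tt, 10 * (1 - exp(-tt / 15)) -
                                    2 * (1 - exp(-tt / 120)))
  expect_equal(classifyKinetics(peak)@label, "peak-plateau")
  # fast phase + persistent slow rise, monotone
  biph <- syntheticTrajectory(tt, 20 * (1 - exp(-tt / 20)) + 30 * tt / 1800)
  expect_equal(classifyKinetics(biph)@label, "biphasic-rising")
  # a plain ramp is neither: gradual
  ramp <- syntheticTrajectory(tt, 30 * tt / 1800)
  expect_equal(classifyKinetics(ramp)@label, "gradual-rising")
  # diagnostics are attached
  d <- classifyKinetics(biph)@diagnostics
  expect_true(all(c("early_slope", "late_slope", "t_half",
                    "overshoot_ratio") %in% names(d)))
  expect_gt(d$early_slope, 5 * d$late_slope)
  short <- syntheticTrajectory(seq(0, 600, 5), seq(0, 10, length.out = 121))
  expect_error(classifyKinetics(short), "too short")
})

test_that("dose panel reproduces the regime structure", {
  pan <- doseResponsePanel(baseParams, beta = 1, gamma = c(1, 100),
                           doses = c(0, 20, 5000), duration = 1800)
  g <- pan$grid
  expect_equal(nrow(g), 6L)
  expect_equal(g$regime[g$dose == 0], rep("flat", 2))
  expect_equal(g$regime[g$gamma == 1 & g$dose == 5000], "biphasic-rising")
  expect_equal(g$regime[g$gamma == 100 & g$dose > 0],
               rep("peak-plateau", 2))
  # end-of-run clearance nondecreasing in dose in each sub-panel (within
  # solver noise; the gamma-scaled panel plateaus)
  for (gm in c(1, 100)) {
    sub <- g[g$gamma == gm, ]
    expect_true(all(diff(sub$finalClearance[order(sub$dose)]) > -0.05))
  }
  expect_error(doseResponsePanel(baseParams, beta = numeric(0)), "nonempty")
})

test_that("dose tunes amplitude but not kinetics for the low-affinity regime", {
  # across above-threshold doses, the spread of time-to-half-max is much
  # narrower at gamma = 100 than in the base case
  pan <- doseResponsePanel(baseParams, beta = 1, gamma = c(1, 100),
                           doses = c(2, 20, 200, 2000, 5000))
  spread <- function(sub) {
    keep <- sub$finalClearance >= 0.1 * max(sub$finalClearance)
    diff(range(sub$tHalf[keep]))
  }
  g <- pan$grid
  expect_lt(spread(g[g$gamma == 100, ]), spread(g[g$gamma == 1, ]))
})

test_that("GBM-mutant scenario predicts a stronger, more gradual response", {
  res <- simulateGbmScenario(baseParams)
  wt30 <- tail(clearance(res$wt), 1)
  gbm30 <- tail(clearance(res$gbm), 1)
  expect_gt(gbm30, wt30)
  thWt <- timeToHalfMax(clearance(res$wt), timePoints(res$wt))$time
  thGbm <- timeToHalfMax(clearance(res$gbm), timePoints(res$gbm))$time
  expect_gt(thGbm, thWt)
  # reverting the mutant scaling to wild-type values gives the wild-type run
  same <- simulateTimecourse(baseParams,
                             ligandSpec("EREG-GBM", dose = 20, beta = 50,
                                        gamma = 100))
  expect_identical(clearance(same), clearance(res$wt))
})

test_that("expression-ratio sweep is linear then saturating", {
  sw <- expressionRatioSweep(baseParams,
                             ratios = 10^seq(-1, 1, length.out = 8),
                             duration = 900)
  expect_true(all(diff(sw$translocation[order(sw$ratio)]) > 0))
  expect_equal(attr(sw, "vary"), "reporter")
  lowRatio <- sw$translocation[1] / sw$ratio[1]
  midRatio <- sw$translocation[2] / sw$ratio[2]
  expect_equal(midRatio / lowRatio, 1, tolerance = 0.05)  # linear regime
  expect_lt(sw$translocation[8] / sw$translocation[7], 1.1)  # saturating
  expect_error(expressionRatioSweep(baseParams, ratios = c(-1, 1)),
               "positive")
})

test_that("k6 scan tracks the pre-formed dimer pool", {
  sc <- scanK6(baseParams, values = 5e-3 * c(0.1, 1, 10),
               ligand = ligandSpec("EGF", dose = 20))
  expect_true(all(diff(sc$N5o) < 0))   # N5o decreases as k6 grows
  # oracle: equilibrium module gives the same pools
  for (i in seq_len(nrow(sc))) {
    eq <- analyticPrestimulusState(updateParameters(baseParams,
                                                    k6 = sc$k6[i]), baseNet)
    expect_equal(sc$N5o[i], eq@N5o, tolerance = 1e-12)
  }
  # a single default value reproduces the plain simulation
  one <- scanK6(baseParams, values = 5e-3,
                ligand = ligandSpec("EGF", dose = 20))
  plain <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 20))
  expect_equal(one$finalClearance, tail(clearance(plain), 1))
  expect_error(scanK6(baseParams, values = numeric(0)), "nonempty")
})

test_that("trajectories round-trip through delimited text", {
  tr <- simulateTimecourse(baseParams, ligandSpec("EGF", dose = 20),
                           duration = 300)
  f <- file.path(tempdir(), "traj.tsv")
  writeTrajectory(tr, f)
  back <- readTrajectory(f)
  expect_equal(timePoints(back), timePoints(tr))
  expect_equal(speciesStates(back), speciesStates(tr), tolerance = 1e-15)
  expect_equal(clearance(back), clearance(tr), tolerance = 1e-15)
  md <- back@metadata
  expect_equal(md$ligand$dose_ng_per_mL, 20)
  expect_equal(md$rtol, 1e-8)
})
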