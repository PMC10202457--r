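# Shared fixtures and independent oracles.

baseParams <- modelParameters()
baseNet <- reactionNetwork()

# Independent oracle for the pre-stimulus dimer pool: solve
# k5 (NE - 2 N5)^2 = k6 N5 for N5 in [0, NE/2] by bisection.
dimerEquilibriumBisect <- function(NE, K) {
  lo <- 0; hi <- NE / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (K * mid - (NE - 2 * mid)^2 > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Random nonnegative state with the ligand slot zeroed (set separately).
randomState <- function(scale = 1e-7) {
  s <- runif(16, 0, scale)
  s[1] <- 0
  s
}

# Build a bare Trajectory carrying a synthetic clearance curve (for
# classifier tests, where only times/clearance matter).
syntheticTrajectory <- function(times, clearanceValues) {
  new("Trajectory", times = times,
      states = matrix(0, length(times), 16,
                      dimnames = list(NULL, paste0("N", 1:16))),
      clearance = clearanceValues, metadata = list(solver = "synthetic"))
}
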