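test_that("species catalogue has the canonical structure", {
  idx <- speciesIndex()
  expect_equal(nrow(idx), 16L)
  expect_equal(idx$label, paste0("N", 1:16))
  expect_equal(sum(idx$is_free_ligand), 1L)
  expect_equal(which(idx$is_free_ligand), 1L)
  expect_equal(sum(idx$is_free_reporter), 1L)
  # receptor-containing species are N3..N16
  expect_true(all(idx$receptor_count[3:16] >= 1))
  expect_equal(idx$receptor_count[1:2], c(0L, 0L))
  # roles: N3 monomer, N4 liganded monomer, N5 ligand-free dimer
  expect_equal(unlist(idx[3, c("receptor_count", "ligand_occupancy",
                               "reporter_occupancy")], use.names = FALSE),
               c(1L, 0L, 0L))
  expect_equal(unlist(idx[4, c("receptor_count", "ligand_occupancy",
                               "reporter_occupancy")], use.names = FALSE),
               c(1L, 1L, 0L))
  expect_equal(unlist(idx[5, c("receptor_count", "ligand_occupancy",
                               "reporter_occupancy")], use.names = FALSE),
               c(2L, 0L, 0L))
  expect_true(idx$is_dimer[5])
  # N4 and N6..N16 are exactly the ligand- and/or reporter-bound receptor
  # species (zero before stimulation)
  bound <- idx$receptor_count >= 1 &
    (idx$ligand_occupancy > 0 | idx$reporter_occupancy > 0)
  expect_equal(which(bound), c(4L, 6:16))
  # occupancy bounded by the number of protomers
  expect_true(all(idx$ligand_occupancy <= idx$receptor_count))
  expect_true(all(idx$reporter_occupancy[3:16] <= idx$receptor_count[3:16]))
})

test_that("reporter association targets only ligand-bound dimers", {
  net <- baseNet
  idx <- species(net)
  rx <- reactions(net)
  assoc <- rx[rx$rate == "k2", ]
  # bimolecular with free reporter; the co-reactant is an activated dimer
  targets <- ifelse(assoc$r1 == 2L, assoc$r2, assoc$r1)
  expect_true(all(idx$is_dimer[targets]))
  expect_true(all(idx$ligand_occupancy[targets] >= 1))
  # and every association has a free tail available
  expect_true(all(idx$reporter_occupancy[targets] <
                    idx$receptor_count[targets]))
})

test_that("ligand scaling multiplies k7 by beta and k3 by gamma only", {
  p <- baseParams
  expect_identical(rateConstants(applyLigandScaling(p, ligandSpec("EGF"))),
                   rateConstants(p))  # identity is bit-identical
  s <- applyLigandScaling(p, ligandSpec("EREG", beta = 50, gamma = 100))
  k0 <- rateConstants(p); k1 <- rateConstants(s)
  expect_equal(k1[["k3"]], 100 * k0[["k3"]])
  expect_equal(k1[["k7"]], 50 * k0[["k7"]])
  expect_identical(k1[c("k1", "k2", "k4", "k5", "k6")],
                   k0[c("k1", "k2", "k4", "k5", "k6")])
  s2 <- applyLigandScaling(p, ligandSpec("x", beta = 1000, gamma = 1))
  expect_equal(rateConstants(s2)[["k7"]], 1000 * k0[["k7"]])
  expect_identical(rateConstants(s2)[["k3"]], k0[["k3"]])
  # composition is multiplicative
  s12 <- applyLigandScaling(applyLigandScaling(p, ligandSpec("a", beta = 5, gamma = 2)),
                            ligandSpec("b", beta = 10, gamma = 50))
  expect_equal(rateConstants(s12)[["k7"]], 50 * k0[["k7"]])
  expect_equal(rateConstants(s12)[["k3"]], 100 * k0[["k3"]])
  expect_error(ligandSpec("bad", beta = 0), "positive")
  expect_error(ligandSpec("bad", gamma = -1), "positive")
})

test_that("unit conversions match independent arithmetic", {
  # oracle: 1 molecule/um^3 = 1.660539e-9 M
  vol <- (4 / 3) * pi * 10^3                     # um^3
  expect_equal(moleculesToConcentration(250000, 10),
               250000 / vol * (1 / 6.02214076e23) / 1e-15,
               tolerance = 1e-12)
  expect_equal(moleculesToConcentration(250000, 10), 9.91e-8,
               tolerance = 1e-3)
  expect_equal(moleculesToConcentration(0, 10), 0)
  expect_equal(moleculesToConcentration(500000, 10),
               2 * moleculesToConcentration(250000, 10))
  expect_error(moleculesToConcentration(10, 0), "positive")

  expect_equal(doseToConcentration(100, 6222), 1.607e-8, tolerance = 1e-3)
  expect_equal(doseToConcentration(0, 6222), 0)
  expect_equal(doseToConcentration(7 * 3, 6222),
               7 * doseToConcentration(3, 6222))
  expect_error(doseToConcentration(1, 0), "positive")
  # LigandSpec derives its concentration with the same rule
  expect_equal(ligandConcentration(ligandSpec("EGF", dose = 100)),
               doseToConcentration(100, 6222))
})

test_that("stoichiometry conserves receptor and reporter exactly", {
  net <- baseNet
  idx <- species(net)
  S <- stoichiometry(net)
  wRec <- idx$receptor_count
  wRep <- idx$reporter_occupancy  # free reporter carries occupancy 1
  expect_true(all(colSums(S * wRec) == 0))   # exact, symbolic
  expect_true(all(colSums(S * wRep) == 0))
  # and therefore the RHS is orthogonal to both conservation vectors
  set.seed(11)
  for (i in 1:25) {
    s <- randomState()
    d <- massActionRHS(s, baseParams, ligandConc = runif(1, 0, 1e-6),
                       network = net)
    expect_lt(abs(sum(wRec * d)), 1e-18)
    expect_lt(abs(sum(wRep * d)), 1e-18)
  }
})

test_that("mass-action derivative behaves at boundary states", {
  net <- baseNet
  zero <- numeric(16)
  expect_equal(unname(massActionRHS(zero, baseParams, 0, net)),
               numeric(16))
  # ligand derivative is clamped to zero even with ligand present
  s <- randomState()
  expect_identical(massActionRHS(s, baseParams, 1e-8, net)[["N1"]], 0)
  # nonnegativity: a species at zero cannot be consumed
  set.seed(42)
  for (i in 1:25) {
    s <- randomState()
    off <- sample(2:16, 5)
    s[off] <- 0
    d <- massActionRHS(s, baseParams, 1e-8, net)
    expect_true(all(d[off] >= 0))
  }
  expect_error(massActionRHS(replace(zero, 3, -1e-9), baseParams, 0, net),
               "nonnegative")
})

test_that("a pure monomer state fluxes only into dimerization, 2:1", {
  net <- baseNet
  s <- numeric(16)
  s[3] <- 1e-7
  d <- massActionRHS(s, baseParams, 0, net)
  expect_equal(d[["N3"]], -2 * d[["N5"]])
  expect_gt(d[["N5"]], 0)
  others <- setdiff(names(d), c("N3", "N5"))
  expect_equal(unname(d[others]), numeric(length(others)))
})

test_that("conserved totals weight receptors and reporters correctly", {
  idx <- speciesIndex()
  s <- numeric(16)
  s[3] <- 3e-8; s[5] <- 2e-8            # monomer + dimer
  tot <- conservedTotals(s, idx)
  expect_equal(unname(tot["receptor_total"]), 3e-8 + 2 * 2e-8)
  expect_equal(unname(tot["reporter_total"]), 0)
  expect_equal(unname(conservedTotals(numeric(16), idx)),
               c(0, 0))
  s2 <- numeric(16)
  s2[2] <- 5e-8; s2[10] <- 1e-8          # free reporter + doubly bound dimer
  expect_equal(unname(conservedTotals(s2, idx)["reporter_total"]),
               5e-8 + 2 * 1e-8)
})

test_that("configuration files round-trip through YAML and JSON", {
  p <- modelParameters(k6 = 7e-3)
  lig <- ligandSpec("EREG", dose = 20, beta = 50, gamma = 100)
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("cfg.", ext))
    writeModelConfig(p, lig, f)
    cfg <- readModelConfig(f)
    expect_equal(rateConstants(cfg$params), rateConstants(p))
    expect_equal(receptorTotal(cfg$params), receptorTotal(p))
    expect_equal(cfg$ligand@beta, 50)
    expect_equal(cfg$ligand@dose, 20)
  }
  bad <- file.path(tempdir(), "bad.yaml")
  yaml::write_yaml(list(parameters = list(k9 = 1)), bad)
  expect_error(readModelConfig(bad), "unknown parameter")
})

test_that("reaction tables export as delimited text", {
  prefix <- file.path(tempdir(), "net")
  fs <- exportReactionTable(baseNet, prefix)
  expect_true(all(file.exists(fs)))
  sp <- read.delim(fs[1])
  expect_equal(nrow(sp), 16L)
  rx <- read.delim(fs[2])
  expect_equal(nrow(rx), nrow(reactions(baseNet)))
})
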