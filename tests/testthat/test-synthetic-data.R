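# Toy structure generators, preset mixtures, planted trajectories.

test_that("the default toy nucleosome has 147 bp and two copies per histone", {
  s <- toyNuc()
  r <- residues(s)
  expect_equal(sum(r$kind == "DNA"), 2 * 147)
  protChains <- unique(r$chain[r$kind == "PROTEIN"])
  expect_length(protChains, 8)
  cm <- toyChainMap()
  expect_setequal(names(cm), c("H2A", "H2B", "H3", "H4"))
  expect_true(all(lengths(cm) == 2))
  s10 <- buildToyNucleosome(nBp = 10)
  expect_equal(sum(residues(s10)$kind == "DNA"), 20)
  expect_error(buildToyNucleosome(nBp = 1), "nBp")
  expect_error(buildToyNucleosome(superhelixRadius = -1), "geometry")
})

test_that("the default build yields both proximal and distal DNA", {
  lab <- classLabels(classifyProximalDistal(toyNuc()))
  expect_gt(sum(lab == "PROXIMAL"), 0)
  expect_gt(sum(lab == "DISTAL"), 0)
})

test_that("no two atoms of different chains clash below 2 Angstrom", {
  a <- atoms(toyNuc(), heavyOnly = TRUE)
  chains <- unique(a$chain)
  for (i in seq_along(chains))
    for (j in seq_len(i - 1)) {
      ci <- as.matrix(a[a$chain == chains[i], c("x", "y", "z")])
      cj <- as.matrix(a[a$chain == chains[j], c("x", "y", "z")])
      expect_gte(parchscape:::.minCrossDist(ci, cj), 2.0)
    }
})

test_that("generated structures survive a write/parse round trip", {
  for (s in list(buildToyNucleosome(nBp = 6),
                 buildToyDinucleosome(nBp = 6, linkerBp = 3))) {
    s2 <- parsePDB(writePDB(s))
    expect_equal(nAtoms(s2), nAtoms(s))
    expect_identical(residues(s2)$resname, residues(s)$resname)
  }
})

test_that("dinucleosome unit labels cover all residues and drive inner/outer", {
  din <- toyDinuc()
  u <- unitLabels(din)
  expect_false(anyNA(u))
  expect_setequal(unique(u), c(1L, 2L))
  lab <- classLabels(classifyInnerOuter(din))
  expect_gt(sum(lab == "INNER"), 0)
  expect_gt(sum(lab == "OUTER"), 0)
  # widely separated units without a linker are entirely OUTER
  far <- buildToyDinucleosome(separation = 200, linkerBp = 0, nBp = 20)
  expect_true(all(classLabels(classifyInnerOuter(far)) == "OUTER"))
  # with a linker, the residues flanking the midpoint face the other unit
  farL <- buildToyDinucleosome(separation = 200, linkerBp = 12, nBp = 20)
  labL <- classLabels(classifyInnerOuter(farL))
  expect_gt(sum(labL == "INNER"), 0)
  expect_error(buildToyDinucleosome(separation = 30), "overlap")
  expect_error(buildToyDinucleosome(separation = -5), "separation")
})

test_that("preset samples are reproducible, truncated, and correctly weighted", {
  expect_identical(samplePreset("nucleosomal_bb", 5000, 1),
                   samplePreset("nucleosomal_bb", 5000, 1))
  expect_error(samplePreset("no_such", 10, 1), "unknown preset")
  for (nm in presetParameters()$preset)
    expect_true(all(samplePreset(nm, 2000, 11) >= 0))
  # component frequencies match the preset weights (binomial oracle)
  d <- samplePreset("nucleosomal_bb", 10000, 2, details = TRUE)
  w <- presetParameters()
  w1 <- w$weight[w$preset == "nucleosomal_bb"][1]
  se <- sqrt(w1 * (1 - w1) / nrow(d))
  expect_lt(abs(mean(d$component == 1) - w1), 3 * se)
})

test_that("preset summary statistics sit in the described regimes", {
  expect_lt(abs(mean(samplePreset("nucleobase", 5000, 2)) - 0.35), 0.05)
  modes <- findModes(parchKDE(samplePreset("nucleosomal_bb", 10000, 3)))
  expect_equal(length(modes), 2)
  expect_lt(max(abs(modes - c(1, 5))), 0.2)
  mf <- findModes(parchKDE(samplePreset("fragment_bb", 10000, 3)))
  expect_equal(length(mf), 1)
  expect_lt(abs(mf - 4), 0.2)
  # the planted shifts point the right way
  expect_lt(mean(samplePreset("methylation_fmc", 3000, 4)),
            mean(samplePreset("methylation_dc", 3000, 4)))
  expect_lt(mean(samplePreset("dinuc_inner_bb", 3000, 5)),
            mean(samplePreset("dinuc_outer_bb", 3000, 5)))
})

test_that("planted trajectories are seed-stable and decay into the window", {
  s <- toyNucSmall()
  pv <- randomPlantedPV(s, seed = 21)
  t1 <- genHydrationTrajectory(s, pv, noiseSd = 0.2, seed = 21)
  t2 <- genHydrationTrajectory(s, pv, noiseSd = 0.2, seed = 21)
  expect_identical(counts(t1), counts(t2))
  # early frames sit above the planted plateau (annealing dewetting)
  cts <- counts(t1)
  expect_gt(mean(cts[, 1]), mean(cts[, ncol(cts)]))
  # coverage mismatch is refused
  short <- pvTable(pvData(pv)[-1, ])
  expect_error(genHydrationTrajectory(s, short), "match")
})

test_that("the generator/scorer loop is the identity at zero noise", {
  s <- toyNucSmall()
  ps <- plantedSystem(s, randomPlantedPV(s, seed = 31), seed = 31)
  expect_identical(pvData(runParch(ps@structure, ps@trajectory))$pv,
                   pvData(ps@plantedPV)$pv)
})

test_that("noisy recovery stays within 0.1 for at least 95% of groups", {
  s <- toyNucSmall()
  pv <- randomPlantedPV(s, seed = 41)
  traj <- genHydrationTrajectory(s, pv, noiseSd = 0.1, seed = 41)
  m <- ceiling(0.1 * ncol(counts(traj)))
  planted <- round(pvData(pv)$pv * m) / m
  err <- abs(pvData(runParch(s, traj))$pv - planted)
  expect_gte(mean(err <= 0.1), 0.95)
})
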