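test_that("the proteome generator is fully deterministic under a seed", {
  cfg <- proteomeSimConfig(nInduced = 15, nNoninduced = 25, nNotCargo = 6)
  a <- simulateProteome(cfg, seed = 99)
  b <- simulateProteome(cfg, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  expect_identical(writeRecords(a$records), writeRecords(b$records))
  c <- simulateProteome(cfg, seed = 100)
  expect_false(identical(writeRecords(a$records), writeRecords(c$records)))
})

test_that("generated records pass the dialect validators", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 20, nNoninduced = 30,
                                            nNotCargo = 9), seed = 31)
  for (i in seq_along(sim$records))
    expect_true(validObject(sim$records[[i]]))
  rep <- validateRecords(text = writeRecords(sim$records))
  expect_true(all(rep$ok))
})

test_that("planted architecture is exactly recoverable by the metrics", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 30, nNoninduced = 40),
                          seed = 37)
  asg <- buildGroups(sim$records, sim$expression)
  mt <- suppressMessages(metricsTable(sim$records, asg))
  tr <- sim$truth[match(mt$accession, sim$truth$accession), ]
  expect_equal(mt$D, tr$D)
  expect_equal(mt$I, tr$I)
  expect_equal(mt$nFreeCys, tr$nFreeCys)
  expect_equal(mt$nCysteines, tr$nCysteines)
  expect_equal(mt$effectiveLength, tr$effectiveLength)
  expect_equal(mt$bondsPer100aa, tr$bondsPer100aa)
  expect_equal(lapply(mt$bondRanges, sort),
               lapply(tr$bondRanges, sort), ignore_attr = TRUE)
})

test_that("group means hit the configured targets (low-dispersion run)", {
  # dispersion below the Poisson floor isolates the mean-targeting logic
  # from the heavy-tailed study-condition spread
  gp <- proteomeSimConfig()$groupParams
  for (cls in names(gp)) for (grp in names(gp[[cls]]))
    gp[[cls]][[grp]]$sdBonds100 <- 0.1
  sim <- simulateProteome(proteomeSimConfig(nInduced = 1200,
                                            nNoninduced = 1200,
                                            nExcludedCargo = 0,
                                            nUnmeasuredCargo = 0,
                                            nNotCargo = 0,
                                            groupParams = gp), seed = 41)
  tr <- sim$truth
  m <- function(cls, grp)
    mean(tr$bondsPer100aa[tr$cargoClass == cls & tr$inductionGroup == grp])
  expect_equal(m("SECRETED", "INDUCED"), 1.30, tolerance = 0.05)
  expect_equal(m("SECRETED", "NONINDUCED"), 0.83, tolerance = 0.05)
  expect_equal(m("MEMBRANE", "INDUCED"), 0.95, tolerance = 0.06)
  expect_equal(m("MEMBRANE", "NONINDUCED"), 0.58, tolerance = 0.06)
  rng <- unlist(tr$bondRanges[tr$cargoClass == "SECRETED" &
                              tr$inductionGroup == "INDUCED"])
  expect_equal(mean(rng), 24.25, tolerance = 0.05)
})

test_that("zero-noise gels recover the planted kinetic curve exactly", {
  g <- simulateGel("secreted", noiseCv = 0, seed = 1)
  for (i in seq_len(nrow(g$truth))) {
    k <- fractionSecreted(g$bands, g$truth$condition[i],
                          g$truth$chase_min[i])
    expect_equal(k$fraction, g$truth$fraction[i], tolerance = 1e-12)
  }
  expect_equal(fractionSecreted(g$bands, "21% O2", 120)$fraction, 0.80)

  gd <- simulateGel("dimer", noiseCv = 0)
  expect_equal(fractionDimer(gd$bands, "21% O2", 60)$fraction, 0.80)
  expect_equal(fractionDimer(gd$bands, "0% O2", 60)$fraction, 0.50)
  gg <- simulateGel("golgi", noiseCv = 0)
  expect_equal(fractionGolgi(gg$bands, "21% O2", 120)$fraction, 0.80)
  expect_equal(fractionGolgi(gg$bands, "0% O2", 120)$fraction, 0.10)
})

test_that("the no-degradation gel conserves total signal at zero noise", {
  g <- simulateGel("secreted", noiseCv = 0)
  tot <- aggregate(intensity ~ condition + replicate + chase_min,
                   g$bands, sum)
  expect_true(all(abs(tot$intensity - 100) < 1e-9))
  # hence fractions relative to the reference sum to the reference total
  sec <- fractionSecreted(g$bands, "21% O2", 60)$fraction
  lys <- with(g$bands, intensity[condition == "21% O2" & replicate == 1 &
                                 chase_min == 60 & band == "LYSATE"]) / 100
  expect_equal(sec + lys, 1, tolerance = 1e-12)
})

test_that("replicate noise propagates to the SEM at the expected scale", {
  set.seed(53)
  cv <- 0.1
  sems <- replicate(60, {
    g <- simulateGel("secreted", noiseCv = cv, replicates = 3)
    fractionSecreted(g$bands, "21% O2", 120)$sem
  })
  # delta-method scale: SEM ~ cv/sqrt(3) * fraction * sqrt(2)-ish
  # (numerator and denominator bands both carry noise); just check order
  expect_gt(mean(sems), 0.8 * cv / sqrt(3) * 0.8)
  expect_lt(mean(sems), 3 * cv / sqrt(3))
})

test_that("cell images are deterministic and carry consistent masks", {
  a <- simulateCells(seed = 61)
  b <- simulateCells(seed = 61)
  expect_identical(imageIntensity(a$image), imageIntensity(b$image))
  expect_identical(backgroundMask(a$image), backgroundMask(b$image))
  expect_true(validObject(a$image))
  expect_equal(a$truth$rimPx, 18L)
  # signal only inside cells
  expect_true(all(imageIntensity(a$image)[backgroundMask(a$image)] == 0))
})

test_that("the planted contrasts point the expected way end to end", {
  dirs <- sapply(1:3, function(s) {
    sim <- simulateProteome(proteomeSimConfig(), seed = 70 + s)
    asg <- buildGroups(sim$records, sim$expression)
    mt <- suppressMessages(metricsTable(sim$records, asg))
    cmp <- suppressMessages(compareAllGroups(mt))
    with(cmp, c(
      bondsSec = meanInduced[1] - meanNoninduced[1],
      bondsMem = meanInduced[2] - meanNoninduced[2],
      rangeSec = meanNoninduced[3] - meanInduced[3],
      fracSec = meanInduced[5] - meanNoninduced[5],
      fracMem = meanInduced[6] - meanNoninduced[6]))
  })
  # averaged over seeds: induced cargo has more bonds/100aa, a larger
  # bonded-cysteine fraction, and shorter secreted bond ranges
  expect_true(all(rowMeans(dirs) > 0))
})
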