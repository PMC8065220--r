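test_that("effective region removes (unions of) cytoplasmic domains", {
  secreted <- ProteinRecord("S1", "G1", 200, signalPeptide = c(1, 20),
                            locations = "secreted")
  expect_length(effectiveRegion(secreted, "SECRETED"), 200L)

  mem <- ProteinRecord("M1", "G2", 250, signalPeptide = c(1, 20),
                       topoDomains = data.frame(
                         start = 201L, end = 250L, note = "Cytoplasmic"),
                       locations = "cell membrane")
  expect_length(effectiveRegion(mem, "MEMBRANE"), 200L)
  # the same domains are kept for a secreted-classed record
  expect_length(effectiveRegion(mem, "SECRETED"), 250L)

  overlap <- ProteinRecord("M2", "G3", 250,
                           topoDomains = data.frame(
                             start = c(10L, 20L), end = c(30L, 40L),
                             note = "Cytoplasmic"),
                           locations = "cell membrane")
  expect_length(effectiveRegion(overlap, "MEMBRANE"), 250L - 31L)
  # non-cytoplasmic notes (e.g. the transmembrane helix) are retained
  tm <- ProteinRecord("M3", "G4", 100,
                      topoDomains = data.frame(start = 10L, end = 30L,
                                               note = "Helical"))
  expect_length(effectiveRegion(tm, "MEMBRANE"), 100L)
})

test_that("worked architectures give the hand-computed metrics", {
  ldlr <- computeMetrics(makeLdlrLikeRecord(), "MEMBRANE")
  expect_equal(ldlr$D, 30L)
  expect_equal(ldlr$I, 0L)
  expect_equal(ldlr$fractionCysBonded, 60 / 63)
  expect_equal(ldlr$nFreeCys, 3L)

  ca9 <- computeMetrics(makeCa9LikeRecord(), "MEMBRANE")
  expect_equal(ca9$D, 1L)
  expect_equal(ca9$I, 1L)
  expect_equal(ca9$fractionCysBonded, 0.6)
  expect_equal(ca9$nFreeCys, 2L)

  two <- ProteinRecord("P1", "G1", 200,
                       cysteinePositions = c(27, 39, 100, 101),
                       disulfides = data.frame(cysA = c(27L, 100L),
                                               cysB = c(39L, 101L),
                                               interchain = FALSE))
  m <- computeMetrics(two, "SECRETED")
  expect_equal(m$bondsPer100aa, 1.0)
  expect_equal(sort(m$bondRanges), c(0L, 11L))
  mDelta <- computeMetrics(two, "SECRETED", rangeConvention = "delta")
  expect_equal(sort(mDelta$bondRanges), c(1L, 12L))
})

test_that("bonds crossing out of the effective region are excluded", {
  r <- ProteinRecord("M1", "G1", 300,
                     cysteinePositions = c(10, 50, 100, 260, 280, 290),
                     topoDomains = data.frame(start = 251L, end = 300L,
                                              note = "Cytoplasmic"),
                     disulfides = data.frame(
                       cysA = c(10L, 100L, 280L), cysB = c(50L, 260L, 290L),
                       interchain = FALSE),
                     locations = "cell membrane")
  m <- computeMetrics(r, "MEMBRANE")
  expect_equal(m$D, 1L)              # 100..260 and 280..290 dropped
  expect_equal(m$effectiveLength, 250L)
  expect_equal(m$nCysteines, 3L)     # 10, 50, 100
  expect_equal(m$nFreeCys, 1L)       # the stranded 100
  expect_equal(m$bondRanges, 39L)
})

test_that("unknown-position bonds count toward D/I but yield no range", {
  r <- ProteinRecord("P1", "G1", 100, cysteinePositions = c(5, 10, 20, 30),
                     disulfides = data.frame(
                       cysA = c(10L, 5L, NA), cysB = c(20L, NA, NA),
                       interchain = c(FALSE, TRUE, TRUE)))
  m <- computeMetrics(r, "SECRETED")
  expect_equal(m$D, 1L)
  expect_equal(m$I, 2L)
  expect_equal(m$bondRanges, 9L)
  expect_equal(m$nFreeCys, 0L)
  expect_equal(m$fractionCysBonded, 1)
})

test_that("a protein with no cysteines has an undefined fraction", {
  r <- ProteinRecord("P0", "G0", 80)
  m <- computeMetrics(r, "SECRETED")
  expect_true(is.na(m$fractionCysBonded))
  expect_equal(m$bondsPer100aa, 0)
})

test_that("compute_metrics matches the brute-force recount on synthetic records", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 60, nNoninduced = 90,
                                            nNotCargo = 15), seed = 13)
  asg <- buildGroups(sim$records, sim$expression)
  mt <- suppressMessages(metricsTable(sim$records, asg))
  for (i in seq_len(nrow(mt))) {
    o <- bruteMetrics(sim$records[[mt$accession[i]]], mt$cargoClass[i])
    expect_identical(mt$D[i], o$D)
    expect_identical(mt$I[i], o$I)
    expect_identical(mt$effectiveLength[i], o$effectiveLength)
    expect_equal(mt$bondsPer100aa[i], o$bondsPer100aa)
    expect_identical(sort(mt$bondRanges[[i]]), o$bondRanges)
    expect_equal(mt$fractionCysBonded[i], o$fractionCysBonded)
    expect_identical(mt$nFreeCys[i], o$nFreeCys)
  }
})

test_that("cysteine accounting is conserved on every generated record", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 40, nNoninduced = 60),
                          seed = 17)
  asg <- buildGroups(sim$records, sim$expression)
  mt <- suppressMessages(metricsTable(sim$records, asg))
  expect_true(all(2L * mt$D + mt$I + mt$nFreeCys == mt$nCysteines))
})

test_that("removing a cysteine-free cytoplasmic domain only rescales lengths", {
  base <- ProteinRecord("P1", "G1", 300, cysteinePositions = c(30, 60, 90),
                        disulfides = data.frame(cysA = 30L, cysB = 60L,
                                                interchain = FALSE),
                        locations = "cell membrane")
  withTail <- ProteinRecord("P1", "G1", 300,
                            cysteinePositions = c(30, 60, 90),
                            topoDomains = data.frame(
                              start = 201L, end = 300L, note = "Cytoplasmic"),
                            disulfides = data.frame(cysA = 30L, cysB = 60L,
                                                    interchain = FALSE),
                            locations = "cell membrane")
  m0 <- computeMetrics(base, "MEMBRANE")
  m1 <- computeMetrics(withTail, "MEMBRANE")
  expect_equal(m1$D, m0$D)
  expect_equal(m1$I, m0$I)
  expect_equal(m1$fractionCysBonded, m0$fractionCysBonded)
  expect_equal(m1$effectiveLength, 200L)
  expect_equal(m1$bondsPer100aa, m0$bondsPer100aa * 300 / 200)
})

test_that("inconsistent bonded-cysteine accounting is an error, not a negative", {
  r <- ProteinRecord("P1", "G1", 100, cysteinePositions = 10,
                     disulfides = data.frame(cysA = NA_integer_,
                                             cysB = NA_integer_,
                                             interchain = FALSE))
  expect_error(computeMetrics(r, "SECRETED"), "inconsistent")
})

test_that("bondRangeTable pools per-bond rows matching the metrics table", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 20, nNoninduced = 20),
                          seed = 19)
  asg <- buildGroups(sim$records, sim$expression)
  mt <- suppressMessages(metricsTable(sim$records, asg))
  rt <- suppressMessages(bondRangeTable(sim$records, asg))
  expect_equal(nrow(rt), sum(lengths(mt$bondRanges)))
  expect_equal(sort(rt$range[rt$accession == mt$accession[1]]),
               sort(mt$bondRanges[[1]]))
  expect_false(anyDuplicated(mt$accession) > 0)
})
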