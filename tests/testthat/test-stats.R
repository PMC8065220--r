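test_that("separated samples give U = 0 and the enumerated p", {
  mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 20)  # 2 of the C(6,3)=20 labelings reach min-U 0
  expect_equal(mw$method, "EXACT")
  expect_false(mw$degenerate)
})

test_that("identical and degenerate samples are flagged with p = 1", {
  mw <- mannWhitney(5, 5)
  expect_equal(mw$p, 1)
  expect_true(mw$degenerate)
  mw2 <- mannWhitney(rep(2, 10), rep(2, 15))
  expect_equal(mw2$p, 1)
  expect_true(mw2$degenerate)
})

test_that("exact p equals full enumeration for all partitions up to n = 8", {
  set.seed(101)
  for (nx in 1:6) {
    for (ny in 1:(8 - nx)) {
      if (ny < 1) next
      for (rep in 1:3) {
        x <- round(rnorm(nx), 6)
        y <- round(rnorm(ny, 0.5), 6)
        if (anyDuplicated(c(x, y))) next
        mw <- mannWhitney(x, y)
        expect_equal(mw$method, "EXACT")
        expect_equal(mw$p, bruteMannWhitneyP(x, y),
                     info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
        # independent reference implementation
        expect_equal(mw$p, wilcox.test(x, y, exact = TRUE)$p.value,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the tie-corrected normal approximation matches the reference", {
  set.seed(202)
  for (rep in 1:50) {
    x <- sample(0:6, 25, replace = TRUE)   # heavy ties
    y <- sample(0:8, 30, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    mw <- mannWhitney(x, y)
    expect_equal(mw$method, "NORMAL_APPROX")
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(mw$p, ref, tolerance = 1e-10)
  }
})

test_that("normal approximation is close to the exact p at n = 20 + 20", {
  set.seed(303)
  for (rep in 1:20) {
    x <- runif(20); y <- runif(20, 0.1, 1.1)
    pExact <- mannWhitney(x, y, exactMax = 40)$p
    pApprox <- mannWhitney(x, y, exactMax = 0)$p
    expect_lt(abs(pApprox - pExact), 0.01)
  }
})

test_that("rank-test invariances hold: symmetry, U complement, monotone maps", {
  set.seed(404)
  for (rep in 1:20) {
    nx <- sample(3:12, 1); ny <- sample(3:12, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.3)
    mw <- mannWhitney(x, y)
    swapped <- mannWhitney(y, x)
    expect_equal(mw$p, swapped$p)
    expect_equal(mw$U, swapped$U)
    # U_x + U_y = nx * ny
    r <- rank(c(x, y))
    Ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    expect_equal(Ux + (nx * ny - Ux), nx * ny)
    # strictly monotone transform of the pooled data leaves p unchanged
    expect_equal(mannWhitney(exp(x), exp(y))$p, mw$p)
    expect_equal(mannWhitney(-x, -y)$p, mw$p)
  }
})

test_that("null rejection rate at alpha = 0.05 is near nominal", {
  set.seed(505)
  p <- replicate(600, mannWhitney(rlnorm(40), rlnorm(40))$p)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("pooled-variance t-test matches the closed form and the reference", {
  st <- studentT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$df, 4)
  expect_equal(st$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  same <- studentT(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # zero pooled variance
  expect_equal(studentT(c(2, 2), c(2, 2))$p, 1)
  degen <- studentT(c(2, 2), c(3, 3))
  expect_equal(degen$p, 0)
  expect_true(degen$degenerate)

  set.seed(606)
  for (rep in 1:100) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), 0.4)
    st <- studentT(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(st$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("compareGroups summarizes and tests the requested contrast", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 40, nNoninduced = 60),
                          seed = 23)
  asg <- buildGroups(sim$records, sim$expression)
  mt <- suppressMessages(metricsTable(sim$records, asg))
  cmp <- suppressMessages(compareGroups(mt, "bondsPer100aa", "SECRETED"))
  expect_s4_class(cmp, "GroupComparison")
  sA <- cmp@summaryA
  vals <- mt$bondsPer100aa[mt$cargoClass == "SECRETED" &
                           mt$inductionGroup == "INDUCED"]
  expect_equal(sA$n, length(vals))
  expect_equal(sA$mean, mean(vals))
  expect_equal(sA$sem, sd(vals) / sqrt(length(vals)))
  expect_equal(sA$median, median(vals))
  expect_equal(unname(c(sA$q25, sA$q75)),
               unname(quantile(vals, c(0.25, 0.75))))
  expect_true(cmp@U >= 0 && cmp@U <= sA$n * cmp@summaryB$n)

  # pooled per-bond ranges vs per-protein means are different contrasts
  pooled <- suppressMessages(compareGroups(mt, "bondRange", "SECRETED"))
  perProt <- suppressMessages(
    compareGroups(mt, "bondRange", "SECRETED",
                  rangeComparison = "perProtein"))
  expect_equal(pooled@summaryA$n,
               sum(lengths(mt$bondRanges[mt$cargoClass == "SECRETED" &
                                         mt$inductionGroup == "INDUCED"])))
  expect_lte(perProt@summaryA$n, sA$n)

  # degenerate shared value
  mt2 <- mt[mt$cargoClass == "SECRETED", ]
  mt2$bondsPer100aa <- 1
  degen <- suppressMessages(compareGroups(mt2, "bondsPer100aa", "SECRETED"))
  expect_equal(degen@p, 1)
  expect_true(degen@degenerate)

  # empty group is an explicit error
  mt3 <- mt[mt$inductionGroup != "INDUCED", ]
  expect_error(suppressMessages(compareGroups(mt3, "bondsPer100aa",
                                              "SECRETED")),
               "empty group")
})

test_that("fraction comparisons omit proteins with undefined fractions", {
  sim <- simulateProteome(proteomeSimConfig(nInduced = 40, nNoninduced = 60),
                          seed = 29)
  asg <- buildGroups(sim$records, sim$expression)
  mt <- suppressMessages(metricsTable(sim$records, asg))
  nUndef <- sum(is.na(mt$fractionCysBonded) & mt$cargoClass == "SECRETED")
  cmp <- suppressMessages(compareGroups(mt, "fractionCysBonded", "SECRETED"))
  nSec <- sum(mt$cargoClass == "SECRETED" &
              mt$inductionGroup %in% c("INDUCED", "NONINDUCED"))
  nUndefCompared <- sum(is.na(mt$fractionCysBonded) &
                        mt$cargoClass == "SECRETED" &
                        mt$inductionGroup %in% c("INDUCED", "NONINDUCED"))
  expect_equal(cmp@summaryA$n + cmp@summaryB$n, nSec - nUndefCompared)
})
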