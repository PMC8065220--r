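# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written in a different style from the package
# implementation (residue-by-residue scans, explicit enumeration).

# LDLR-style architecture: 30 intrachain bonds concentrated N-terminally,
# 3 free cysteines (63 cysteines total), secreted-type record.
makeLdlrLikeRecord <- function() {
  a <- 20L + 25L * (0:29)
  b <- a + 11L
  ProteinRecord("LDLR_LIKE", "LDLR", 860L,
                cysteinePositions = c(a, b, c(800L, 810L, 820L)),
                signalPeptide = c(1L, 21L),
                disulfides = data.frame(cysA = a, cysB = b,
                                        interchain = FALSE),
                locations = "cell membrane")
}

# CA9-style monomer: one intrachain bond, one interchain (dimer) cysteine,
# two free cysteines (5 cysteines total).
makeCa9LikeRecord <- function() {
  ProteinRecord("CA9_LIKE", "CA9", 459L,
                cysteinePositions = c(41L, 119L, 299L, 350L, 400L),
                signalPeptide = c(1L, 37L),
                disulfides = data.frame(
                  cysA = c(119L, 41L), cysB = c(299L, NA),
                  interchain = c(FALSE, TRUE)),
                locations = "cell membrane")
}

# Independent brute-force recount of the disulfide metrics: residue scan
# for the region, explicit loops over features.
bruteMetrics <- function(record, cargoClass,
                         rangeConvention = "between") {
  L <- proteinLength(record)
  td <- topoDomains(record)
  inRegion <- vapply(seq_len(L), function(i) {
    if (!identical(cargoClass, "MEMBRANE")) return(TRUE)
    for (j in seq_len(nrow(td))) {
      if (grepl("cytoplasmic", td$note[j], ignore.case = TRUE) &&
          i >= td$start[j] && i <= td$end[j]) return(FALSE)
    }
    TRUE
  }, logical(1))
  nCys <- 0L
  for (p in cysteinePositions(record)) if (inRegion[p]) nCys <- nCys + 1L
  ds <- disulfides(record)
  D <- 0L; I <- 0L; ranges <- integer(0)
  for (j in seq_len(nrow(ds))) {
    a <- ds$cysA[j]; b <- ds$cysB[j]
    aOut <- !is.na(a) && !inRegion[a]
    bOut <- !is.na(b) && !inRegion[b]
    if (aOut || bOut) next
    if (ds$interchain[j]) {
      I <- I + 1L
    } else {
      D <- D + 1L
      if (!is.na(a) && !is.na(b))
        ranges <- c(ranges, if (rangeConvention == "between")
          abs(b - a) - 1L else abs(b - a))
    }
  }
  effLen <- sum(inRegion)
  list(D = D, I = I, effectiveLength = effLen,
       bondsPer100aa = 100 * (D + I) / effLen,
       bondRanges = sort(ranges),
       fractionCysBonded = if (nCys > 0) (2 * D + I) / nCys else NA_real_,
       nCysteines = nCys, nFreeCys = nCys - 2L * D - I)
}

# Exhaustive permutation oracle for the two-sided Mann-Whitney p:
# enumerate every labeling of the pooled values as x/y via combn and count
# labelings whose min-U is at most the observed one.
bruteMannWhitneyP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  minU <- function(idx) {
    r <- rank(pooled)
    Ux <- sum(r[idx]) - nx * (nx + 1) / 2
    min(Ux, nx * ny - Ux)
  }
  obs <- minU(seq_len(nx))
  sets <- utils::combn(nx + ny, nx)
  hits <- sum(apply(sets, 2, function(idx) minU(idx) <= obs + 1e-9))
  hits / ncol(sets)
}

# Pixel-exhaustive band oracle: a cell pixel is in the membrane band iff
# its squared Euclidean distance to some background pixel is <= r^2.
bruteMembraneBand <- function(backgroundMask, r) {
  d <- dim(backgroundMask)
  bg <- which(backgroundMask, arr.ind = TRUE)
  band <- matrix(FALSE, d[1], d[2])
  if (!nrow(bg)) return(band)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (backgroundMask[i, j]) next
      d2 <- (bg[, 1] - i)^2 + (bg[, 2] - j)^2
      if (min(d2) <= r^2) band[i, j] <- TRUE
    }
  }
  band
}

# small deterministic band table for densitometry arithmetic
makeBandTable <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(condition = r[[1]], replicate = as.integer(r[[2]]),
               chase_min = as.numeric(r[[3]]), band = r[[4]],
               intensity = as.numeric(r[[5]]), stringsAsFactors = FALSE)))
}
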