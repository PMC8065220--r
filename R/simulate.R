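## Synthetic-data generators with known ground truth.
##
## Every input class consumed by the pipeline (annotated proteome +
## expression table, gel band tables, calibrated images) can be generated
## here with planted ground truth, so the full analysis is testable
## without any external downloads. Generator defaults target the study
## conditions: group sizes 112 induced / 313 noninduced, group means of
## 1.3/0.83 (secreted) and 0.95/0.58 (membrane) disulfide bonds per 100
## amino acids, mean secreted bond ranges of 24.25/31.02 residues, and
## group dispersions calibrated once so the standard errors of the group
## means at those sizes are 0.16/0.08 (secreted) and 0.19/0.08 (membrane).

.defaultGroupParams <- function() {
  list(
    SECRETED = list(
      INDUCED    = list(meanBonds100 = 1.30, sdBonds100 = 1.69,
                        meanRange = 24.25, meanFreeCys = 1),
      NONINDUCED = list(meanBonds100 = 0.83, sdBonds100 = 1.42,
                        meanRange = 31.02, meanFreeCys = 3)),
    MEMBRANE = list(
      INDUCED    = list(meanBonds100 = 0.95, sdBonds100 = 2.01,
                        meanRange = 28, meanFreeCys = 1),
      NONINDUCED = list(meanBonds100 = 0.58, sdBonds100 = 1.42,
                        meanRange = 28, meanFreeCys = 3))
  )
}

#' Configuration for the synthetic proteome generator
#'
#' Defaults plant the study conditions: 112 hypoxia-induced and 313
#' noninduced cargo proteins split evenly between secreted and membrane
#' classes, group mean bonds/100aa of 1.3/0.83 (secreted) and 0.95/0.58
#' (membrane), mean secreted bond ranges 24.25/31.02, fewer free cysteines
#' in induced proteins (Poisson means 1 vs 3), and group SDs chosen so the
#' SEMs of the group means at the default sizes are 0.16/0.08 (secreted)
#' and 0.19/0.08 (membrane).
#'
#' @param nInduced,nNoninduced Planted group sizes (defaults 112, 313).
#' @param secretedFraction Fraction of each induction group that is
#'   secreted (the rest is membrane-bound); default 0.5.
#' @param nExcludedCargo,nUnmeasuredCargo,nNotCargo Extra records planted
#'   with intermediate fold changes, no measurement, or failing the cargo
#'   filter.
#' @param groupParams Nested list `[[cargoClass]][[inductionGroup]]` with
#'   `meanBonds100`, `sdBonds100`, `meanRange`, `meanFreeCys`.
#' @param pInterchain Probability that a planted bond is interchain.
#' @param lengthMeanlog,lengthSdlog Log-normal residue-length parameters.
#' @param seed Default seed used by [simulateProteome()].
#' @return A list of class `"ProteomeSimConfig"`.
#' @export
proteomeSimConfig <- function(nInduced = 112, nNoninduced = 313,
                              secretedFraction = 0.5,
                              nExcludedCargo = 20, nUnmeasuredCargo = 20,
                              nNotCargo = 60,
                              groupParams = .defaultGroupParams(),
                              pInterchain = 0.05,
                              lengthMeanlog = log(450), lengthSdlog = 0.45,
                              seed = NULL) {
  stopifnot(nInduced >= 1, nNoninduced >= 1,
            secretedFraction >= 0, secretedFraction <= 1)
  for (cls in names(groupParams))
    for (grp in names(groupParams[[cls]])) {
      p <- groupParams[[cls]][[grp]]
      stopifnot(p$meanBonds100 > 0, p$meanRange > 0, p$meanFreeCys >= 0)
    }
  structure(list(nInduced = nInduced, nNoninduced = nNoninduced,
                 secretedFraction = secretedFraction,
                 nExcludedCargo = nExcludedCargo,
                 nUnmeasuredCargo = nUnmeasuredCargo,
                 nNotCargo = nNotCargo, groupParams = groupParams,
                 pInterchain = pInterchain,
                 lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
                 seed = seed),
            class = "ProteomeSimConfig")
}

# gamma shape for the per-protein bond rate: total variance of bonds/100aa
# = Poisson part (mean * 100 / E[effective length]) + rate variance
# (mean^2 / shape); invert for the shape given the target SD.
.gammaShape <- function(meanB, sdB, expEffLen) {
  gv <- sdB^2 - meanB * 100 / expEffLen
  if (gv <= 0) Inf else meanB^2 / gv
}

.makeSynthRecord <- function(accession, gene, cargoClass, par, config,
                             shape, withSignal = TRUE,
                             locationsOverride = NULL) {
  isMem <- cargoClass == "MEMBRANE"
  Lmin <- if (isMem) 230L else 150L
  L <- max(Lmin, as.integer(round(stats::rlnorm(1, config$lengthMeanlog,
                                                config$lengthSdlog))))
  spEnd <- sample(18:28, 1)
  sp <- if (withSignal) c(1L, spEnd) else NULL
  tmLen <- 21L
  td <- .emptyTopoDomains()
  ct <- 0L
  if (isMem) {
    ct <- sample(30:min(80L, L - spEnd - tmLen - 60L), 1)
    exEnd <- L - ct - tmLen
    td <- data.frame(start = c(spEnd + 1L, exEnd + 1L, L - ct + 1L),
                     end = c(exEnd, L - ct, L),
                     note = c("Extracellular", "Helical", "Cytoplasmic"),
                     stringsAsFactors = FALSE)
  }
  # cysteine/bond placement region: mature extracellular part
  s0 <- spEnd + 1L
  s1 <- if (isMem) L - ct - tmLen else L
  effLen <- L - ct  # cytosolic portion removed; SP and TM retained

  rate <- if (is.finite(shape))
    stats::rgamma(1, shape = shape, rate = shape / par$meanBonds100)
  else par$meanBonds100
  nBonds <- stats::rpois(1, rate * effLen / 100)
  nInter <- stats::rbinom(1, nBonds, config$pInterchain)
  nIntra <- nBonds - nInter

  free <- rep(TRUE, L)
  free[-(s0:s1)] <- FALSE
  bondsA <- integer(0); bondsB <- integer(0)
  pGeom <- 1 / (1 + par$meanRange)
  for (j in seq_len(nIntra)) {
    placed <- FALSE
    for (try in 1:50) {
      g <- min(stats::rgeom(1, pGeom), s1 - s0 - 1L)
      cand <- s0:(s1 - g - 1L)
      a <- cand[sample.int(length(cand), 1)]
      b <- a + g + 1L
      if (free[a] && free[b]) {
        bondsA <- c(bondsA, a); bondsB <- c(bondsB, b)
        free[c(a, b)] <- FALSE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # fall back to any free pair; drop the bond if none remains
      avail <- which(free)
      if (length(avail) >= 2L) {
        ab <- sort(avail[sample.int(length(avail), 2)])
        bondsA <- c(bondsA, ab[1]); bondsB <- c(bondsB, ab[2])
        free[ab] <- FALSE
      }
    }
  }
  interPos <- integer(0)
  for (j in seq_len(nInter)) {
    avail <- which(free)
    if (!length(avail)) break
    p <- avail[sample.int(length(avail), 1)]
    interPos <- c(interPos, p)
    free[p] <- FALSE
  }
  nFreeWanted <- stats::rpois(1, par$meanFreeCys)
  avail <- which(free)
  freePos <- if (nFreeWanted > 0 && length(avail))
    avail[sample.int(length(avail), min(nFreeWanted, length(avail)))]
  else integer(0)
  cytPos <- integer(0)
  if (isMem) {
    nCyt <- stats::rpois(1, 0.7)
    cytRegion <- (L - ct + 1L):L
    if (nCyt > 0)
      cytPos <- cytRegion[sample.int(length(cytRegion), min(nCyt, ct))]
  }

  ds <- .emptyDisulfides()
  if (length(bondsA))
    ds <- rbind(ds, data.frame(cysA = bondsA, cysB = bondsB,
                               interchain = FALSE))
  if (length(interPos))
    ds <- rbind(ds, data.frame(cysA = interPos, cysB = NA_integer_,
                               interchain = TRUE))
  locs <- if (!is.null(locationsOverride)) locationsOverride
          else if (isMem) "cell membrane" else "secreted"
  rec <- ProteinRecord(
    accession = accession, geneId = gene, length = L,
    cysteinePositions = c(bondsA, bondsB, interPos, freePos, cytPos),
    signalPeptide = sp, topoDomains = td, disulfides = ds,
    locations = locs)
  D <- length(bondsA); I <- length(interPos)
  truth <- list(
    accession = accession, geneId = gene, cargoClass = cargoClass,
    D = D, I = I, nFreeCys = length(freePos),
    nCysteines = 2L * D + I + length(freePos),
    effectiveLength = as.integer(effLen),
    bondsPer100aa = 100 * (D + I) / effLen,
    bondRanges = as.integer(bondsB - bondsA - 1L))
  list(record = rec, truth = truth)
}

.exprRows <- function(gene, group, cellLines = c("HCT116", "HepG2")) {
  lines <- sample(cellLines)
  nL <- 1L + stats::rbinom(1, 1, 0.7)
  fc <- switch(group,
    INDUCED = c(stats::runif(1, 2.2, 9),
                if (nL > 1) stats::runif(1, 0.4, 5.5)),
    NONINDUCED = stats::runif(nL, 0.45, 1.15),
    EXCLUDED = stats::runif(nL, 1.25, 1.95),
    UNMEASURED = numeric(0),
    OTHER = if (stats::rbinom(1, 1, 0.5)) stats::runif(nL, 0.5, 4)
            else numeric(0))
  if (!length(fc))
    return(NULL)
  list(gene_id = rep(gene, length(fc)), cell_line = lines[seq_along(fc)],
       fold_change = fc)
}

#' Simulate an annotated proteome with expression table
#'
#' Generates cargo records (plus excluded/unmeasured/non-cargo
#' distractors), a matching expression table, and exact per-record ground
#' truth. Lengths are log-normal; per-protein bond counts are
#' gamma-mixed Poisson (matching the configured group mean and SD of
#' bonds/100aa); bond partner offsets are geometric around the configured
#' mean range; cysteine positions are placed consistently (bond endpoints,
#' interchain cysteines, free thiols, plus occasional cytosolic cysteines
#' on membrane proteins that the effective-region exclusion must remove).
#' Fold changes are drawn so planted groups pass the selection thresholds.
#' Fully deterministic under a fixed seed.
#'
#' @param config A [proteomeSimConfig()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with elements `records` ([ProteinSet-class]),
#'   `expression` (data.frame `gene_id`, `cell_line`, `fold_change`),
#'   `truth` (data.frame keyed by accession with planted `cargoClass`,
#'   `inductionGroup`, `D`, `I`, `nFreeCys`, `nCysteines`,
#'   `effectiveLength`, `bondsPer100aa` and list column `bondRanges`) and
#'   `config`.
#' @export
simulateProteome <- function(config = proteomeSimConfig(),
                             seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  expEffLenSec <- exp(config$lengthMeanlog + config$lengthSdlog^2 / 2)
  expEffLenMem <- expEffLenSec - 55  # mean cytosolic tail
  plan <- list()
  addPlan <- function(n, cls, grp) {
    if (n > 0) plan[[length(plan) + 1L]] <<-
      data.frame(cargoClass = rep(cls, n), inductionGroup = grp,
                 stringsAsFactors = FALSE)
  }
  nIndSec <- round(config$nInduced * config$secretedFraction)
  nNonSec <- round(config$nNoninduced * config$secretedFraction)
  addPlan(nIndSec, "SECRETED", "INDUCED")
  addPlan(config$nInduced - nIndSec, "MEMBRANE", "INDUCED")
  addPlan(nNonSec, "SECRETED", "NONINDUCED")
  addPlan(config$nNoninduced - nNonSec, "MEMBRANE", "NONINDUCED")
  nExSec <- round(config$nExcludedCargo / 2)
  addPlan(nExSec, "SECRETED", "EXCLUDED")
  addPlan(config$nExcludedCargo - nExSec, "MEMBRANE", "EXCLUDED")
  nUnSec <- round(config$nUnmeasuredCargo / 2)
  addPlan(nUnSec, "SECRETED", "UNMEASURED")
  addPlan(config$nUnmeasuredCargo - nUnSec, "MEMBRANE", "UNMEASURED")
  addPlan(config$nNotCargo, "NOT_CARGO", "OTHER")
  plan <- do.call(rbind, plan)

  records <- vector("list", nrow(plan))
  truths <- vector("list", nrow(plan))
  exprs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    acc <- sprintf("SYN%05d", i)
    gene <- sprintf("GENE%05d", i)
    cls <- plan$cargoClass[i]
    grp <- plan$inductionGroup[i]
    if (cls == "NOT_CARGO") {
      # distractors cycling through the three failure modes of the filter
      variant <- i %% 3L
      par <- config$groupParams$SECRETED$NONINDUCED
      shape <- .gammaShape(par$meanBonds100, par$sdBonds100, expEffLenSec)
      out <- switch(as.character(variant),
        "0" = .makeSynthRecord(acc, gene, "SECRETED", par, config, shape,
                               withSignal = FALSE,
                               locationsOverride = "cytoplasm"),
        "1" = .makeSynthRecord(acc, gene, "SECRETED", par, config, shape,
                               locationsOverride = c("secreted",
                                 "endoplasmic reticulum")),
        "2" = .makeSynthRecord(acc, gene, "SECRETED", par, config, shape,
                               locationsOverride = "nucleus"))
      out$truth$cargoClass <- "NOT_CARGO"
    } else {
      archGrp <- if (grp %in% c("INDUCED", "NONINDUCED")) grp
                 else "NONINDUCED"
      par <- config$groupParams[[cls]][[archGrp]]
      expEff <- if (cls == "MEMBRANE") expEffLenMem else expEffLenSec
      shape <- .gammaShape(par$meanBonds100, par$sdBonds100, expEff)
      out <- .makeSynthRecord(acc, gene, cls, par, config, shape)
    }
    out$truth$inductionGroup <- grp
    records[[i]] <- out$record
    truths[[i]] <- out$truth
    exprs[[i]] <- .exprRows(gene, grp)
  }
  pick <- function(f, mode) vapply(truths, `[[`, vector(mode, 1L), f)
  truth <- data.frame(
    accession = pick("accession", "character"),
    geneId = pick("geneId", "character"),
    cargoClass = pick("cargoClass", "character"),
    inductionGroup = pick("inductionGroup", "character"),
    D = pick("D", "integer"), I = pick("I", "integer"),
    nFreeCys = pick("nFreeCys", "integer"),
    nCysteines = pick("nCysteines", "integer"),
    effectiveLength = pick("effectiveLength", "integer"),
    bondsPer100aa = pick("bondsPer100aa", "double"),
    bondRanges = I(lapply(truths, `[[`, "bondRanges")),
    stringsAsFactors = FALSE)
  exprs <- exprs[!vapply(exprs, is.null, logical(1))]
  expression <- data.frame(
    gene_id = unlist(lapply(exprs, `[[`, "gene_id"), use.names = FALSE),
    cell_line = unlist(lapply(exprs, `[[`, "cell_line"), use.names = FALSE),
    fold_change = unlist(lapply(exprs, `[[`, "fold_change"),
                         use.names = FALSE),
    stringsAsFactors = FALSE)
  list(records = ProteinSet(records), expression = expression,
       truth = truth, config = config)
}

#' Simulate a pulse-chase gel band table
#'
#' Plants a two-band conversion (lysate to secreted, monomer to dimer, or
#' ER form to Golgi form) with total signal conserved per lane set (no
#' degradation) and multiplicative log-normal noise of a given
#' coefficient of variation. The planted converted fraction follows a
#' normalized saturating exponential
#' `f(t) = fTarget * (1 - exp(-k t)) / (1 - exp(-k tMax))`, so the
#' terminal fraction equals `fTarget` exactly; at `noiseCv = 0` the
#' fraction functions recover the planted curve exactly.
#'
#' @param mode `"secreted"`, `"dimer"` or `"golgi"`; selects the band
#'   pair and the default chase times, targets and rates. Mode defaults
#'   plant the study-condition terminal fractions (secreted: 0.80 at
#'   120 min in both conditions; dimer: 0.80 normoxia / 0.50 anoxia at
#'   60 min; Golgi: 0.80 / 0.10 at 120 min).
#' @param conditions Condition labels.
#' @param times Chase times in minutes.
#' @param fTarget Named terminal fractions per condition.
#' @param rate Named first-order rates (per min) per condition.
#' @param total Conserved total lane intensity (arbitrary units).
#' @param replicates Number of replicates.
#' @param noiseCv Coefficient of variation of the multiplicative band
#'   noise (0 = none).
#' @param seed Integer seed.
#' @return List with `bands` (a valid band table), `truth` (data.frame
#'   `condition`, `chase_min`, `fraction` planted) and `mode`.
#' @export
simulateGel <- function(mode = c("secreted", "dimer", "golgi"),
                        conditions = c("21% O2", "0% O2"),
                        times = NULL, fTarget = NULL, rate = NULL,
                        total = 100, replicates = 3, noiseCv = 0.1,
                        seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  def <- switch(mode,
    secreted = list(times = c(15, 30, 60, 120),
                    bands = c("SECRETED", "LYSATE"),
                    fTarget = c(0.80, 0.80), rate = c(0.030, 0.018)),
    dimer = list(times = c(0, 15, 30, 60),
                 bands = c("DIMER", "MONOMER"),
                 fTarget = c(0.80, 0.50), rate = c(0.05, 0.03)),
    golgi = list(times = c(0, 30, 60, 120),
                 bands = c("GOLGI_FORM", "ER_FORM"),
                 fTarget = c(0.80, 0.10), rate = c(0.03, 0.03)))
  if (is.null(times)) times <- def$times
  if (is.null(fTarget)) fTarget <- stats::setNames(def$fTarget, conditions)
  if (is.null(rate)) rate <- stats::setNames(def$rate, conditions)
  stopifnot(all(rate >= 0), all(fTarget >= 0), all(fTarget <= 1))
  tMax <- max(times)
  s <- sqrt(log(1 + noiseCv^2))
  noise <- function(n) if (noiseCv > 0)
    stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s) else rep(1, n)

  rows <- list(); truthRows <- list()
  for (cond in conditions) {
    k <- rate[[cond]]
    f <- if (k > 0) fTarget[[cond]] * (1 - exp(-k * times)) /
           (1 - exp(-k * tMax)) else rep(0, length(times))
    truthRows[[cond]] <- data.frame(condition = cond, chase_min = times,
                                    fraction = f, stringsAsFactors = FALSE)
    for (rep in seq_len(replicates)) {
      prod <- total * f * noise(length(times))
      src <- total * (1 - f) * noise(length(times))
      rows[[paste(cond, rep)]] <- data.frame(
        condition = cond, replicate = rep,
        chase_min = rep(times, 2L),
        band = rep(def$bands, each = length(times)),
        intensity = c(prod, src), stringsAsFactors = FALSE)
    }
  }
  bands <- do.call(rbind, rows)
  rownames(bands) <- NULL
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  validateBandTable(bands)
  list(bands = bands, truth = truth, mode = mode)
}

#' Simulate a calibrated fluorescence image of cells
#'
#' Draws non-overlapping disk cells on an empty background. A rim of
#' configurable width just inside each cell edge receives
#' `membraneFractionTrue` of the cell's integrated signal (uniformly); the
#' interior receives the rest. Optional Poisson pixel noise. The rim width
#' defaults to the 2 um membrane-band definition so the planted fraction
#' is directly recoverable by [localizationRatio()].
#'
#' @param nCells Number of cells (default 2).
#' @param membraneFractionTrue Planted membrane signal fraction in
#'   `[0, 1]`.
#' @param umPerPixel Pixel size (default 0.1083 um).
#' @param imageSize Image side in pixels.
#' @param rimUm Rim width in micrometres (default 2).
#' @param radiusUm Range of cell radii in micrometres.
#' @param signalPerCell Integrated photon count per cell.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @param maxTries Bounded retries for non-overlapping placement.
#' @return List with `image` ([LabeledImage-class]) and `truth` (list:
#'   `membraneFractionTrue`, `rimPx`, per-cell centers and radii in px).
#' @export
simulateCells <- function(nCells = 2, membraneFractionTrue = 0.8,
                          umPerPixel = 0.1083, imageSize = 384,
                          rimUm = 2.0, radiusUm = c(6.5, 9),
                          signalPerCell = 2e5,
                          noise = c("poisson", "none"), seed = NULL,
                          maxTries = 200) {
  noise <- match.arg(noise)
  stopifnot(membraneFractionTrue >= 0, membraneFractionTrue <= 1)
  if (!is.null(seed)) set.seed(seed)
  rimPx <- as.integer(round(rimUm / umPerPixel))
  # bounded global restarts: re-draw radii and all centers on failure so a
  # large first cell cannot wedge the placement
  placed <- FALSE
  for (attempt in seq_len(maxTries)) {
    rPx <- stats::runif(nCells, radiusUm[1], radiusUm[2]) / umPerPixel
    if (any(rPx <= rimPx))
      stop("cell radius must exceed the rim width")
    margin <- ceiling(max(rPx)) + 2
    if (2 * margin >= imageSize)
      stop("image too small for the requested cell radii")
    centers <- matrix(NA_real_, nCells, 2)
    ok <- TRUE
    for (i in seq_len(nCells)) {
      hit <- FALSE
      for (try in 1:25) {
        c0 <- stats::runif(2, margin, imageSize - margin)
        if (i == 1L || all(sqrt(rowSums((centers[seq_len(i - 1), ,
              drop = FALSE] - rep(c0, each = i - 1))^2)) >
              rPx[seq_len(i - 1)] + rPx[i] + 3)) {
          centers[i, ] <- c0
          hit <- TRUE
          break
        }
      }
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) { placed <- TRUE; break }
  }
  if (!placed)
    stop("could not place ", nCells, " non-overlapping cells after ",
         maxTries, " restarts")
  xs <- matrix(seq_len(imageSize), imageSize, imageSize)
  ys <- t(xs)
  disks <- lapply(seq_len(nCells), function(i) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    d2 <= rPx[i]^2
  })
  inCell <- Reduce(`|`, disks)
  # rim pixels by the same criterion the membrane band uses: Euclidean
  # distance to the nearest background pixel at most the rim width
  distToBg <- as.matrix(EBImage::imageData(
    EBImage::distmap(inCell * 1, metric = "euclidean")))
  rimAll <- inCell & distToBg <= rimPx
  lambda <- matrix(0, imageSize, imageSize)
  for (i in seq_len(nCells)) {
    rim <- disks[[i]] & rimAll
    interior <- disks[[i]] & !rimAll
    lambda[rim] <- lambda[rim] +
      membraneFractionTrue * signalPerCell / sum(rim)
    if (any(interior))
      lambda[interior] <- lambda[interior] +
        (1 - membraneFractionTrue) * signalPerCell / sum(interior)
  }
  intensity <- if (noise == "poisson") {
    matrix(stats::rpois(length(lambda), lambda), imageSize, imageSize)
  } else lambda
  img <- LabeledImage(intensity, !inCell, umPerPixel)
  list(image = img,
       truth = list(membraneFractionTrue = membraneFractionTrue,
                    rimPx = rimPx, centers = centers, radiiPx = rPx))
}
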