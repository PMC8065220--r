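## Per-protein disulfide-architecture metrics.
##
## For membrane proteins the cytosolic portions (topological domains whose
## note matches "Cytoplasmic") are excluded before counting: cysteines,
## bonds and the per-100-aa denominator are all taken over the remaining
## effective region, and a bond is dropped iff either of its cysteines lies
## outside it. The signal peptide is retained by default (it can be trimmed
## via `trimSignalPeptide`). All cysteines not annotated in a disulfide are
## treated as free thiols.

#' Effective residue region of a cargo protein
#'
#' For `MEMBRANE` cargo, all residues minus the union of topological
#' domains whose note matches "Cytoplasmic" (case-insensitive; overlapping
#' domains are unioned, never double-counted). For any other class, all
#' residues.
#'
#' @param record A [ProteinRecord-class].
#' @param cargoClass `"SECRETED"`, `"MEMBRANE"` or `"NOT_CARGO"`.
#' @param trimSignalPeptide Also remove the signal peptide span
#'   (default `FALSE`).
#' @return Sorted integer vector of residue indices.
#' @export
effectiveRegion <- function(record, cargoClass = "SECRETED",
                            trimSignalPeptide = FALSE) {
  keep <- rep(TRUE, proteinLength(record))
  if (identical(cargoClass, "MEMBRANE")) {
    td <- topoDomains(record)
    cyt <- td[grepl("cytoplasmic", td$note, ignore.case = TRUE), ,
              drop = FALSE]
    for (i in seq_len(nrow(cyt)))
      keep[cyt$start[i]:cyt$end[i]] <- FALSE
  }
  if (trimSignalPeptide && length(signalPeptide(record)) == 2L) {
    sp <- signalPeptide(record)
    keep[sp[1]:sp[2]] <- FALSE
  }
  which(keep)
}

#' Disulfide metrics for a single protein
#'
#' Counts intrachain (`D`) and interchain (`I`) disulfides, the effective
#' length, bonds per 100 amino acids, bond ranges, fraction of cysteines
#' bonded and free cysteines, restricted to the [effectiveRegion()] of the
#' record.
#'
#' Bonds with one or both positions unknown still count toward `D`/`I`
#' (the architecture exists even when coordinates are missing) but
#' contribute no range. Bond ranges are computed only for intrachain bonds
#' with both positions known, by default as the number of residues strictly
#' between the paired cysteines (`cysB - cysA - 1`); set
#' `rangeConvention = "delta"` for the alternative `cysB - cysA`.
#'
#' When no cysteine lies in the effective region, `fractionCysBonded` is
#' `NA` and the record should be omitted from fraction comparisons (done
#' automatically by [compareGroups()]).
#'
#' @param record A [ProteinRecord-class].
#' @param cargoClass Cargo class controlling cytosolic exclusion.
#' @param rangeConvention `"between"` (default) or `"delta"`.
#' @param trimSignalPeptide Passed to [effectiveRegion()].
#' @return Named list of class `"DisulfideMetrics"`: `accession`, `D`,
#'   `I`, `effectiveLength`, `bondsPer100aa`, `bondRanges`,
#'   `fractionCysBonded`, `nCysteines`, `nFreeCys`.
#' @examples
#' r <- ProteinRecord("P1", "G1", 200, cysteinePositions = c(27, 39, 80, 120),
#'                    disulfides = data.frame(cysA = c(27L, 80L),
#'                                            cysB = c(39L, 120L),
#'                                            interchain = FALSE))
#' m <- computeMetrics(r, "SECRETED")
#' m$bondsPer100aa  # 1.0
#' m$bondRanges     # 11, 39
#' @export
computeMetrics <- function(record, cargoClass = "SECRETED",
                           rangeConvention = c("between", "delta"),
                           trimSignalPeptide = FALSE) {
  rangeConvention <- match.arg(rangeConvention)
  region <- effectiveRegion(record, cargoClass, trimSignalPeptide)
  if (!length(region))
    stop("effective region of ", accession(record), " is empty")
  inRegion <- logical(proteinLength(record))
  inRegion[region] <- TRUE

  cys <- cysteinePositions(record)
  cys <- cys[inRegion[cys]]
  nCys <- length(cys)

  ds <- disulfides(record)
  keepBond <- function(a, b) {
    # excluded iff a *known* endpoint lies outside the region
    (is.na(a) || inRegion[a]) && (is.na(b) || inRegion[b])
  }
  D <- 0L; I <- 0L
  ranges <- integer(0)
  for (i in seq_len(nrow(ds))) {
    a <- ds$cysA[i]; b <- ds$cysB[i]
    if (ds$interchain[i]) {
      if (keepBond(a, b)) I <- I + 1L
    } else if (keepBond(a, b)) {
      D <- D + 1L
      if (!is.na(a) && !is.na(b))
        ranges <- c(ranges, if (rangeConvention == "between") b - a - 1L
                    else b - a)
    }
  }

  nFree <- nCys - 2L * D - I
  if (nFree < 0L)
    stop("record ", accession(record), " annotates more bonded cysteines ",
         "(2D + I = ", 2L * D + I, ") than cysteines present (", nCys,
         "); inconsistent annotation")
  structure(list(
    accession = accession(record),
    D = D, I = I,
    effectiveLength = length(region),
    bondsPer100aa = 100 * (D + I) / length(region),
    bondRanges = ranges,
    fractionCysBonded = if (nCys > 0L) (2 * D + I) / nCys else NA_real_,
    nCysteines = nCys,
    nFreeCys = nFree
  ), class = "DisulfideMetrics")
}

#' Per-protein metrics table for grouped cargo
#'
#' One row per cargo protein (non-cargo records are skipped), carrying the
#' record's cargo class and induction group alongside its
#' [computeMetrics()] fields. Bond ranges are kept as a list column; use
#' [bondRangeTable()] for the pooled long-format companion used in
#' per-bond range comparisons.
#'
#' @param records A [ProteinSet-class].
#' @param assignments data.frame from [buildGroups()].
#' @param rangeConvention,trimSignalPeptide Passed to [computeMetrics()].
#' @return data.frame keyed by accession with columns `accession`,
#'   `cargoClass`, `inductionGroup`, `D`, `I`, `effectiveLength`,
#'   `bondsPer100aa`, `fractionCysBonded`, `nCysteines`, `nFreeCys` and
#'   list column `bondRanges`.
#' @export
metricsTable <- function(records, assignments,
                         rangeConvention = c("between", "delta"),
                         trimSignalPeptide = FALSE) {
  rangeConvention <- match.arg(rangeConvention)
  cargo <- assignments[assignments$cargoClass != "NOT_CARGO", , drop = FALSE]
  n <- nrow(cargo)
  ms <- lapply(seq_len(n), function(i)
    computeMetrics(records[[cargo$accession[i]]], cargo$cargoClass[i],
                   rangeConvention, trimSignalPeptide))
  pick <- function(f, mode) vapply(ms, `[[`, vector(mode, 1L), f)
  out <- data.frame(
    accession = if (n) pick("accession", "character") else character(0),
    cargoClass = cargo$cargoClass,
    inductionGroup = cargo$inductionGroup,
    D = if (n) pick("D", "integer") else integer(0),
    I = if (n) pick("I", "integer") else integer(0),
    effectiveLength = if (n) pick("effectiveLength", "integer") else integer(0),
    bondsPer100aa = if (n) pick("bondsPer100aa", "double") else numeric(0),
    fractionCysBonded = if (n) pick("fractionCysBonded", "double") else numeric(0),
    nCysteines = if (n) pick("nCysteines", "integer") else integer(0),
    nFreeCys = if (n) pick("nFreeCys", "integer") else integer(0),
    bondRanges = I(lapply(ms, `[[`, "bondRanges")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pooled per-bond range table
#'
#' Long-format companion to [metricsTable()]: one row per intrachain bond
#' with both positions known, used for pooled per-bond range comparisons.
#'
#' @inheritParams metricsTable
#' @return data.frame with columns `accession`, `cargoClass`,
#'   `inductionGroup`, `range`.
#' @export
bondRangeTable <- function(records, assignments,
                           rangeConvention = c("between", "delta"),
                           trimSignalPeptide = FALSE) {
  mt <- metricsTable(records, assignments, rangeConvention,
                     trimSignalPeptide)
  n <- vapply(mt$bondRanges, length, integer(1))
  data.frame(accession = rep(mt$accession, n),
             cargoClass = rep(mt$cargoClass, n),
             inductionGroup = rep(mt$inductionGroup, n),
             range = unlist(mt$bondRanges, use.names = FALSE),
             stringsAsFactors = FALSE)
}
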