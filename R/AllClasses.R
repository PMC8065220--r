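#' @import methods
#' @importFrom S4Vectors SimpleList
#' @importClassesFrom S4Vectors SimpleList
NULL

.emptyTopoDomains <- function() {
  data.frame(start = integer(0), end = integer(0), note = character(0),
             stringsAsFactors = FALSE)
}

.emptyDisulfides <- function() {
  data.frame(cysA = integer(0), cysB = integer(0), interchain = logical(0),
             stringsAsFactors = FALSE)
}

#' Protein annotation record
#'
#' One protein's annotation as used throughout the package: residue length,
#' cysteine positions, signal peptide, topological domains, disulfide bonds
#' and subcellular locations. All residue coordinates are 1-based inclusive
#' (UniProt convention). Disulfide bonds with one or both positions unknown
#' are retained with `NA` coordinates and handled downstream per metric.
#'
#' @slot accession Unique protein accession.
#' @slot geneId Gene identifier used to join expression tables.
#' @slot length Sequence length in residues.
#' @slot cysteinePositions Sorted unique 1-based cysteine positions.
#' @slot signalPeptide Integer of length 0 (absent) or 2, `c(start, end)`.
#' @slot topoDomains data.frame with columns `start`, `end`, `note`
#'   (e.g. "Cytoplasmic", "Extracellular", "Helical").
#' @slot disulfides data.frame with columns `cysA`, `cysB` (1-based residue
#'   positions, `NA` when unknown) and logical `interchain`.
#' @slot locations Character vector of subcellular location phrases.
#'
#' @aliases ProteinRecord-class
#' @exportClass ProteinRecord
setClass("ProteinRecord",
  slots = c(
    accession = "character",
    geneId = "character",
    length = "integer",
    cysteinePositions = "integer",
    signalPeptide = "integer",
    topoDomains = "data.frame",
    disulfides = "data.frame",
    locations = "character"
  ),
  prototype = list(
    accession = NA_character_, geneId = NA_character_, length = 1L,
    cysteinePositions = integer(0), signalPeptide = integer(0),
    topoDomains = .emptyTopoDomains(), disulfides = .emptyDisulfides(),
    locations = character(0)
  )
)

setValidity("ProteinRecord", function(object) {
  msg <- character(0)
  if (length(object@accession) != 1L || is.na(object@accession) ||
      !nzchar(object@accession))
    msg <- c(msg, "'accession' must be a non-empty scalar string")
  if (length(object@length) != 1L || is.na(object@length) ||
      object@length < 1L)
    msg <- c(msg, "'length' must be a positive integer")
  L <- object@length
  cys <- object@cysteinePositions
  if (anyNA(cys) || any(cys < 1L) || any(cys > L))
    msg <- c(msg, "cysteine positions must lie within [1, length]")
  if (is.unsorted(cys, strictly = TRUE) && length(cys) > 1L)
    msg <- c(msg, "cysteine positions must be strictly increasing")
  sp <- object@signalPeptide
  if (!length(sp) %in% c(0L, 2L)) {
    msg <- c(msg, "'signalPeptide' must have length 0 or 2")
  } else if (length(sp) == 2L) {
    if (anyNA(sp) || sp[1] < 1L || sp[2] > L || sp[1] > sp[2])
      msg <- c(msg, "signal peptide span must satisfy 1 <= start <= end <= length")
  }
  td <- object@topoDomains
  if (!all(c("start", "end", "note") %in% names(td))) {
    msg <- c(msg, "'topoDomains' must have columns start, end, note")
  } else if (nrow(td)) {
    if (anyNA(td$start) || anyNA(td$end) ||
        any(td$start < 1L) || any(td$end > L) || any(td$start > td$end))
      msg <- c(msg, "topological domain spans must satisfy 1 <= start <= end <= length")
  }
  ds <- object@disulfides
  if (!all(c("cysA", "cysB", "interchain") %in% names(ds))) {
    msg <- c(msg, "'disulfides' must have columns cysA, cysB, interchain")
  } else if (nrow(ds)) {
    known <- c(ds$cysA[!is.na(ds$cysA)], ds$cysB[!is.na(ds$cysB)])
    if (any(known < 1L) || any(known > L))
      msg <- c(msg, "disulfide positions must lie within [1, length]")
    both <- !is.na(ds$cysA) & !is.na(ds$cysB) & !ds$interchain
    if (any(both & ds$cysA >= ds$cysB))
      msg <- c(msg, "intrachain disulfides with known positions require cysA < cysB")
    if (length(cys) && length(known) && !all(known %in% cys))
      msg <- c(msg, "known disulfide positions must be cysteine positions")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinRecord
#'
#' @param accession,geneId Identifier strings.
#' @param length Sequence length in residues.
#' @param cysteinePositions Integer vector of 1-based cysteine positions
#'   (sorted internally).
#' @param signalPeptide `NULL` for none, or `c(start, end)`.
#' @param topoDomains data.frame with columns `start`, `end`, `note`.
#' @param disulfides data.frame with columns `cysA`, `cysB`, `interchain`.
#' @param locations Character vector of subcellular locations.
#' @return A validated [ProteinRecord-class] object.
#' @examples
#' ProteinRecord("P1", "G1", 100, cysteinePositions = c(10, 40),
#'               signalPeptide = c(1, 20),
#'               disulfides = data.frame(cysA = 10L, cysB = 40L,
#'                                       interchain = FALSE),
#'               locations = "secreted")
#' @export
ProteinRecord <- function(accession, geneId = NA_character_, length,
                          cysteinePositions = integer(0),
                          signalPeptide = NULL,
                          topoDomains = .emptyTopoDomains(),
                          disulfides = .emptyDisulfides(),
                          locations = character(0)) {
  if (is.null(signalPeptide)) signalPeptide <- integer(0)
  ds <- as.data.frame(disulfides, stringsAsFactors = FALSE)
  if (nrow(ds)) {
    ds$cysA <- as.integer(ds$cysA)
    ds$cysB <- as.integer(ds$cysB)
    ds$interchain <- as.logical(ds$interchain)
    # canonical orientation for known intrachain bonds
    flip <- !is.na(ds$cysA) & !is.na(ds$cysB) & ds$cysA > ds$cysB
    if (any(flip)) {
      tmp <- ds$cysA[flip]
      ds$cysA[flip] <- ds$cysB[flip]
      ds$cysB[flip] <- tmp
    }
  } else {
    ds <- .emptyDisulfides()
  }
  td <- as.data.frame(topoDomains, stringsAsFactors = FALSE)
  if (nrow(td)) {
    td$start <- as.integer(td$start)
    td$end <- as.integer(td$end)
    td$note <- as.character(td$note)
  } else {
    td <- .emptyTopoDomains()
  }
  new("ProteinRecord",
      accession = as.character(accession),
      geneId = as.character(geneId),
      length = as.integer(length),
      cysteinePositions = sort(unique(as.integer(cysteinePositions))),
      signalPeptide = as.integer(signalPeptide),
      topoDomains = td,
      disulfides = ds,
      locations = as.character(locations))
}

#' Collection of protein records
#'
#' A list-like container of [ProteinRecord-class] objects with unique
#' accessions, built on [S4Vectors::SimpleList].
#'
#' @aliases ProteinSet-class
#' @exportClass ProteinSet
setClass("ProteinSet", contains = "SimpleList",
         prototype = prototype(elementType = "ProteinRecord"))

setValidity("ProteinSet", function(object) {
  ok <- vapply(object, is, logical(1), class2 = "ProteinRecord")
  if (!all(ok))
    return("all elements must be ProteinRecord objects")
  acc <- vapply(object, slot, character(1), name = "accession")
  if (anyDuplicated(acc))
    return(paste0("duplicate accession(s): ",
                  paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  TRUE
})

#' Construct a ProteinSet
#'
#' @param ... ProteinRecord objects, or a single list of them.
#' @return A [ProteinSet-class].
#' @export
ProteinSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "ProteinRecord"))
    args <- args[[1]]
  acc <- vapply(args, function(r) r@accession, character(1))
  sl <- S4Vectors::SimpleList(args)
  names(sl) <- acc
  new("ProteinSet", sl)
}

#' Two-group comparison result
#'
#' Result of comparing one disulfide metric between hypoxia-induced and
#' noninduced cargo: per-group summaries (n, mean, SEM, median, IQR) and a
#' two-sided Mann-Whitney test.
#'
#' @slot metric Name of the compared metric.
#' @slot cargoClass Cargo class the comparison was restricted to.
#' @slot groupA,groupB Labels of the two groups.
#' @slot summaryA,summaryB Named lists: `n`, `mean`, `sem`, `median`,
#'   `q25`, `q75`.
#' @slot U Mann-Whitney statistic, `min(U_a, U_b)`.
#' @slot p Two-sided p-value.
#' @slot method `"EXACT"` or `"NORMAL_APPROX"`.
#' @slot degenerate `TRUE` when all pooled values coincide.
#'
#' @aliases GroupComparison-class
#' @exportClass GroupComparison
setClass("GroupComparison",
  slots = c(metric = "character", cargoClass = "character",
            groupA = "character", groupB = "character",
            summaryA = "list", summaryB = "list",
            U = "numeric", p = "numeric", method = "character",
            degenerate = "logical"))

setValidity("GroupComparison", function(object) {
  msg <- character(0)
  nA <- object@summaryA$n; nB <- object@summaryB$n
  if (!is.null(nA) && !is.null(nB) &&
      (object@U < 0 || object@U > nA * nB))
    msg <- c(msg, "U must lie in [0, nA*nB]")
  if (object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Calibrated single-channel fluorescence image
#'
#' An intensity raster plus a same-shaped logical background mask
#' (`TRUE` = background) and a pixel size in micrometres.
#'
#' @slot intensity Non-negative numeric matrix.
#' @slot backgroundMask Logical matrix, `TRUE` for background pixels.
#' @slot umPerPixel Pixel size in micrometres (e.g. 0.1083).
#'
#' @aliases LabeledImage-class
#' @exportClass LabeledImage
setClass("LabeledImage",
  slots = c(intensity = "matrix", backgroundMask = "matrix",
            umPerPixel = "numeric"))

setValidity("LabeledImage", function(object) {
  msg <- character(0)
  if (!is.numeric(object@intensity))
    msg <- c(msg, "'intensity' must be numeric")
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "'intensity' must be non-negative")
  if (!is.logical(object@backgroundMask))
    msg <- c(msg, "'backgroundMask' must be logical")
  if (!identical(dim(object@intensity), dim(object@backgroundMask)))
    msg <- c(msg, "intensity and background mask must have the same shape")
  if (length(object@umPerPixel) != 1L || is.na(object@umPerPixel) ||
      object@umPerPixel <= 0)
    msg <- c(msg, "'umPerPixel' must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImage
#'
#' @param intensity Non-negative numeric matrix.
#' @param backgroundMask Logical matrix of the same shape (`TRUE` =
#'   background).
#' @param umPerPixel Pixel size in micrometres.
#' @return A [LabeledImage-class].
#' @export
LabeledImage <- function(intensity, backgroundMask, umPerPixel) {
  storage.mode(intensity) <- "double"
  mode(backgroundMask) <- "logical"
  new("LabeledImage", intensity = intensity,
      backgroundMask = backgroundMask, umPerPixel = as.numeric(umPerPixel))
}

#' Membrane localization result
#'
#' @slot cellMask Logical matrix, whole-cell area (complement of background).
#' @slot membraneMask Logical matrix, membrane band (subset of cellMask).
#' @slot membraneFraction Integrated-intensity fraction in `[0, 1]`.
#' @slot meanIntensityRatio Mean-intensity ratio (band mean / cell mean).
#'
#' @aliases LocalizationResult-class
#' @exportClass LocalizationResult
setClass("LocalizationResult",
  slots = c(cellMask = "matrix", membraneMask = "matrix",
            membraneFraction = "numeric", meanIntensityRatio = "numeric"))

setValidity("LocalizationResult", function(object) {
  msg <- character(0)
  if (any(object@membraneMask & !object@cellMask))
    msg <- c(msg, "membrane mask must be a subset of the cell mask")
  mf <- object@membraneFraction
  if (!is.na(mf) && (mf < 0 || mf > 1))
    msg <- c(msg, "membraneFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
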