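#' Accessors for ProteinRecord and image classes
#'
#' Accessor generics for the package's S4 classes. Slots are never accessed
#' directly by user code.
#'
#' @param x A [ProteinRecord-class], [LabeledImage-class] or
#'   [LocalizationResult-class] object as appropriate.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
#' @rdname accessors
#' @export
setGeneric("cysteinePositions", function(x) standardGeneric("cysteinePositions"))
#' @rdname accessors
#' @export
setGeneric("signalPeptide", function(x) standardGeneric("signalPeptide"))
#' @rdname accessors
#' @export
setGeneric("topoDomains", function(x) standardGeneric("topoDomains"))
#' @rdname accessors
#' @export
setGeneric("disulfides", function(x) standardGeneric("disulfides"))
#' @rdname accessors
#' @export
setGeneric("locations", function(x) standardGeneric("locations"))
#' @rdname accessors
#' @export
setGeneric("imageIntensity", function(x) standardGeneric("imageIntensity"))
#' @rdname accessors
#' @export
setGeneric("backgroundMask", function(x) standardGeneric("backgroundMask"))
#' @rdname accessors
#' @export
setGeneric("umPerPixel", function(x) standardGeneric("umPerPixel"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("membraneMask", function(x) standardGeneric("membraneMask"))
#' @rdname accessors
#' @export
setGeneric("membraneFraction", function(x) standardGeneric("membraneFraction"))
#' @rdname accessors
#' @export
setGeneric("meanIntensityRatio", function(x) standardGeneric("meanIntensityRatio"))

#' @rdname accessors
setMethod("accession", "ProteinRecord", function(x) x@accession)
#' @rdname accessors
setMethod("geneId", "ProteinRecord", function(x) x@geneId)
#' @rdname accessors
setMethod("proteinLength", "ProteinRecord", function(x) x@length)
#' @rdname accessors
setMethod("cysteinePositions", "ProteinRecord", function(x) x@cysteinePositions)
#' @rdname accessors
setMethod("signalPeptide", "ProteinRecord", function(x) x@signalPeptide)
#' @rdname accessors
setMethod("topoDomains", "ProteinRecord", function(x) x@topoDomains)
#' @rdname accessors
setMethod("disulfides", "ProteinRecord", function(x) x@disulfides)
#' @rdname accessors
setMethod("locations", "ProteinRecord", function(x) x@locations)

#' @rdname accessors
setMethod("imageIntensity", "LabeledImage", function(x) x@intensity)
#' @rdname accessors
setMethod("backgroundMask", "LabeledImage", function(x) x@backgroundMask)
#' @rdname accessors
setMethod("umPerPixel", "LabeledImage", function(x) x@umPerPixel)

#' @rdname accessors
setMethod("cellMask", "LocalizationResult", function(x) x@cellMask)
#' @rdname accessors
setMethod("membraneMask", "LocalizationResult", function(x) x@membraneMask)
#' @rdname accessors
setMethod("membraneFraction", "LocalizationResult", function(x) x@membraneFraction)
#' @rdname accessors
setMethod("meanIntensityRatio", "LocalizationResult", function(x) x@meanIntensityRatio)

setMethod("show", "ProteinRecord", function(object) {
  ds <- object@disulfides
  cat("ProteinRecord", object@accession,
      sprintf("(gene %s, %d aa)\n", object@geneId, object@length))
  cat(sprintf("  cysteines: %d | disulfides: %d intrachain, %d interchain\n",
              length(object@cysteinePositions),
              sum(!ds$interchain), sum(ds$interchain)))
  cat(sprintf("  signal peptide: %s | topo domains: %d | locations: %s\n",
              if (length(object@signalPeptide))
                paste(object@signalPeptide, collapse = "..") else "none",
              nrow(object@topoDomains),
              if (length(object@locations))
                paste(object@locations, collapse = "; ") else "none"))
  invisible(NULL)
})

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object), "protein records\n")
  if (length(object)) {
    acc <- vapply(object, accession, character(1))
    n <- min(5L, length(acc))
    cat("  ", paste(acc[seq_len(n)], collapse = ", "),
        if (length(acc) > n) ", ..." else "", "\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "GroupComparison", function(object) {
  fmtg <- function(lbl, s)
    sprintf("  %s: n=%d mean=%.4g (SEM %.3g) median=%.4g IQR [%.4g, %.4g]\n",
            lbl, s$n, s$mean, s$sem, s$median, s$q25, s$q75)
  cat(sprintf("GroupComparison: %s (%s)\n", object@metric, object@cargoClass))
  cat(fmtg(object@groupA, object@summaryA))
  cat(fmtg(object@groupB, object@summaryB))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.4g (%s%s)\n",
              object@U, object@p, object@method,
              if (object@degenerate) ", DEGENERATE" else ""))
  invisible(NULL)
})

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("LabeledImage %d x %d px (%.4f um/pixel), %.1f%% background\n",
              d[1], d[2], object@umPerPixel,
              100 * mean(object@backgroundMask)))
  invisible(NULL)
})

setMethod("show", "LocalizationResult", function(object) {
  cat(sprintf(paste0("LocalizationResult: membrane fraction %.3f, ",
                     "mean-intensity ratio %.3f\n"),
              object@membraneFraction, object@meanIntensityRatio))
  cat(sprintf("  cell area %d px, membrane band %d px\n",
              sum(object@cellMask), sum(object@membraneMask)))
  invisible(NULL)
})
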