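## ER-cargo filtering and hypoxia-induction grouping.
##
## ER cargo is defined operationally: a signal peptide, a subcellular
## location matching "secreted" or "cell membrane", and no location
## matching "endoplasmic reticulum" or "golgi apparatus" (residents of the
## secretory organelles are excluded). Induction grouping cross-references
## gene-level fold changes after 24 h anoxia in two cell lines.

#' Cargo-selection configuration
#'
#' Thresholds and location vocabularies used by [classifyCargo()],
#' [assignInduction()] and [buildGroups()]. Fold changes are linear ratios
#' (a "twofold" induction is 2.0, not log2). Location matching is
#' case-insensitive substring matching of each vocabulary term against the
#' record's location phrases.
#'
#' @param inducedThreshold Fold change above which a gene counts as
#'   hypoxia-induced in a cell line (default 2).
#' @param noninducedThreshold Fold change below which a gene counts as
#'   noninduced (default 1.2); must be `< inducedThreshold`.
#' @param cargoLocations Location terms defining cargo (default
#'   `"secreted"`, `"cell membrane"`).
#' @param excludedLocations Location terms whose presence disqualifies a
#'   record (default `"endoplasmic reticulum"`, `"golgi apparatus"`).
#' @return A list of class `"SelectionConfig"`.
#' @export
selectionConfig <- function(inducedThreshold = 2,
                            noninducedThreshold = 1.2,
                            cargoLocations = c("secreted", "cell membrane"),
                            excludedLocations = c("endoplasmic reticulum",
                                                  "golgi apparatus")) {
  stopifnot(is.numeric(inducedThreshold), is.numeric(noninducedThreshold))
  if (noninducedThreshold >= inducedThreshold)
    stop("'noninducedThreshold' must be below 'inducedThreshold'")
  structure(list(inducedThreshold = inducedThreshold,
                 noninducedThreshold = noninducedThreshold,
                 cargoLocations = tolower(cargoLocations),
                 excludedLocations = tolower(excludedLocations)),
            class = "SelectionConfig")
}

# which vocabulary terms occur (case-insensitive substring) in any of the
# record's location phrases
.matchedTerms <- function(locs, vocab) {
  if (!length(locs) || !length(vocab)) return(character(0))
  locs <- tolower(locs)
  vocab[vapply(vocab, function(v) any(grepl(v, locs, fixed = TRUE)),
               logical(1))]
}

#' Classify a protein record as ER cargo
#'
#' `NOT_CARGO` when the record lacks a signal peptide, matches no cargo
#' location, or matches any excluded location (exclusion dominates);
#' otherwise `MEMBRANE` when "cell membrane" matches, else `SECRETED`.
#'
#' @param record A [ProteinRecord-class].
#' @param config A [selectionConfig()].
#' @return `"SECRETED"`, `"MEMBRANE"` or `"NOT_CARGO"`.
#' @export
classifyCargo <- function(record, config = selectionConfig()) {
  if (!length(signalPeptide(record))) return("NOT_CARGO")
  locs <- locations(record)
  if (length(.matchedTerms(locs, config$excludedLocations)))
    return("NOT_CARGO")
  hits <- .matchedTerms(locs, config$cargoLocations)
  if (!length(hits)) return("NOT_CARGO")
  if ("cell membrane" %in% hits) "MEMBRANE" else "SECRETED"
}

.validateExpressionTable <- function(table) {
  need <- c("gene_id", "cell_line", "fold_change")
  if (!all(need %in% names(table)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table)) {
    if (any(!is.finite(table$fold_change)) || any(table$fold_change <= 0))
      stop("fold changes must be positive finite ratios")
    if (anyDuplicated(table[, c("gene_id", "cell_line")]))
      stop("at most one fold change per (gene_id, cell_line)")
  }
  invisible(table)
}

#' Assign the hypoxia-induction group of a cargo record
#'
#' `INDUCED` when the gene exceeds the induced threshold in at least one
#' cell line; `NONINDUCED` when it is below the noninduced threshold in
#' every cell line with a measurement; `UNMEASURED` when the gene is absent
#' from the table; `EXCLUDED` for intermediate fold changes (the two
#' printed bands are not exhaustive).
#'
#' @param record A [ProteinRecord-class] (must be cargo).
#' @param table Expression data.frame with columns `gene_id`, `cell_line`,
#'   `fold_change` (linear ratios, 24 h anoxia vs control).
#' @param config A [selectionConfig()].
#' @return One of `"INDUCED"`, `"NONINDUCED"`, `"EXCLUDED"`, `"UNMEASURED"`.
#' @export
assignInduction <- function(record, table, config = selectionConfig()) {
  .validateExpressionTable(table)
  fc <- table$fold_change[table$gene_id == geneId(record)]
  if (!length(fc)) return("UNMEASURED")
  if (any(fc > config$inducedThreshold)) return("INDUCED")
  if (all(fc < config$noninducedThreshold)) return("NONINDUCED")
  "EXCLUDED"
}

#' Partition protein records into cargo/induction groups
#'
#' Applies [classifyCargo()] and [assignInduction()] to every record and
#' returns one assignment row per record. The partition over cargo records
#' is exhaustive and disjoint; `EXCLUDED` and `UNMEASURED` cargo are
#' reported but conventionally omitted from induced-vs-noninduced
#' comparisons. Non-cargo records get `NA` as induction group.
#'
#' @param records A [ProteinSet-class] or list of records.
#' @param table Expression data.frame (see [assignInduction()]).
#' @param config A [selectionConfig()].
#' @return data.frame with columns `accession`, `geneId`, `cargoClass`,
#'   `inductionGroup`.
#' @examples
#' r <- ProteinRecord("P1", "G1", 120, signalPeptide = c(1, 20),
#'                    locations = "secreted")
#' expr <- data.frame(gene_id = "G1", cell_line = "HCT116", fold_change = 3.1)
#' buildGroups(ProteinSet(list(r)), expr)
#' @export
buildGroups <- function(records, table, config = selectionConfig()) {
  .validateExpressionTable(table)
  n <- length(records)
  acc <- character(n); gid <- character(n)
  cls <- character(n); grp <- rep(NA_character_, n)
  fcByGene <- split(table$fold_change, table$gene_id)
  for (i in seq_len(n)) {
    r <- records[[i]]
    acc[i] <- accession(r)
    gid[i] <- geneId(r)
    cls[i] <- classifyCargo(r, config)
    if (cls[i] != "NOT_CARGO") {
      fc <- fcByGene[[gid[i]]]
      grp[i] <- if (is.null(fc)) "UNMEASURED"
        else if (any(fc > config$inducedThreshold)) "INDUCED"
        else if (all(fc < config$noninducedThreshold)) "NONINDUCED"
        else "EXCLUDED"
    }
  }
  data.frame(accession = acc, geneId = gid, cargoClass = cls,
             inductionGroup = grp, stringsAsFactors = FALSE)
}
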