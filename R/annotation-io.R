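## Annotation-dialect I/O.
##
## The interchange format is a UTF-8 TSV modeled on UniProt tab downloads:
## one protein per row, feature strings in flat-file style, semicolon-
## separated within a cell. Columns:
##   accession, gene_id, length, sequence, cys_positions, signal_peptide,
##   topo_domains, disulfides, locations
## `sequence` and `cys_positions` are optional; cysteine positions are
## derived from the sequence when present, otherwise read from the explicit
## column. Feature strings look like "SIGNAL 1..22",
## "TOPO_DOM 101..150 /note=Cytoplasmic", "DISULFID 27..39",
## "DISULFID 54..? /note=Interchain". Unknown positions are written "?".

.DIALECT_COLUMNS <- c("accession", "gene_id", "length", "sequence",
                      "cys_positions", "signal_peptide", "topo_domains",
                      "disulfides", "locations")

# Split a feature cell on ";" and re-attach bare "/note=..." continuation
# tokens to the preceding feature (both "A /note=X" and "A; /note=X" occur
# in the wild).
.featureTokens <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  out <- character(0)
  for (p in parts) {
    if (startsWith(p, "/note=") && length(out)) {
      out[length(out)] <- paste(out[length(out)], p)
    } else {
      out <- c(out, p)
    }
  }
  out
}

.parseFeature <- function(token, expectedKinds) {
  m <- regmatches(token, regexec(
    "^(SIGNAL|TOPO_DOM|DISULFID)\\s+(\\?|[0-9]+)\\.\\.(\\?|[0-9]+)(?:\\s+/note=(.*))?$",
    token))[[1]]
  if (!length(m))
    stop("malformed feature string: '", token, "'", call. = FALSE)
  kind <- m[2]
  if (!kind %in% expectedKinds)
    stop("feature kind '", kind, "' not allowed in this column", call. = FALSE)
  a <- if (m[3] == "?") NA_integer_ else as.integer(m[3])
  b <- if (m[4] == "?") NA_integer_ else as.integer(m[4])
  if (kind != "DISULFID" && (is.na(a) || is.na(b)))
    stop("unknown positions ('?') are only permitted for DISULFID features",
         call. = FALSE)
  note <- if (length(m) >= 5 && nzchar(m[5])) m[5] else NA_character_
  list(kind = kind, start = a, end = b, note = note)
}

.parseRow <- function(row) {
  L <- suppressWarnings(as.integer(row[["length"]]))
  if (is.na(L) || L < 1L)
    stop("'length' must be a positive integer", call. = FALSE)

  seq <- row[["sequence"]]
  hasSeq <- !is.na(seq) && nzchar(seq)
  if (hasSeq) {
    if (nchar(seq) != L)
      stop("sequence length (", nchar(seq), ") disagrees with 'length' (",
           L, ")", call. = FALSE)
    cys <- which(strsplit(toupper(seq), "")[[1]] == "C")
  } else {
    cp <- row[["cys_positions"]]
    cys <- if (is.na(cp) || !nzchar(trimws(cp))) integer(0) else
      as.integer(trimws(strsplit(cp, ",", fixed = TRUE)[[1]]))
    if (anyNA(cys))
      stop("'cys_positions' must be a comma-separated list of integers",
           call. = FALSE)
  }

  sp <- NULL
  spTokens <- .featureTokens(row[["signal_peptide"]])
  if (length(spTokens) > 1L)
    stop("at most one SIGNAL feature per record", call. = FALSE)
  if (length(spTokens) == 1L) {
    f <- .parseFeature(spTokens, "SIGNAL")
    if (f$start > f$end)
      stop("SIGNAL span has start > end", call. = FALSE)
    sp <- c(f$start, f$end)
  }

  td <- .emptyTopoDomains()
  for (tok in .featureTokens(row[["topo_domains"]])) {
    f <- .parseFeature(tok, "TOPO_DOM")
    if (f$start > f$end)
      stop("TOPO_DOM span has start > end", call. = FALSE)
    td <- rbind(td, data.frame(start = f$start, end = f$end,
                               note = if (is.na(f$note)) "" else f$note,
                               stringsAsFactors = FALSE))
  }

  ds <- .emptyDisulfides()
  for (tok in .featureTokens(row[["disulfides"]])) {
    f <- .parseFeature(tok, "DISULFID")
    inter <- !is.na(f$note) && grepl("interchain", f$note, ignore.case = TRUE)
    if (!inter && !is.na(f$start) && !is.na(f$end) && f$start > f$end)
      stop("DISULFID span has start > end", call. = FALSE)
    ds <- rbind(ds, data.frame(cysA = f$start, cysB = f$end,
                               interchain = inter, stringsAsFactors = FALSE))
  }

  locCell <- row[["locations"]]
  locs <- if (is.na(locCell) || !nzchar(trimws(locCell))) character(0) else {
    v <- trimws(strsplit(locCell, ";", fixed = TRUE)[[1]])
    v[nzchar(v)]
  }

  ProteinRecord(accession = row[["accession"]], geneId = row[["gene_id"]],
                length = L, cysteinePositions = cys, signalPeptide = sp,
                topoDomains = td, disulfides = ds, locations = locs)
}

#' Parse an annotation-dialect table into protein records
#'
#' Reads the package's UniProt-style TSV dialect (see Details) and returns
#' one validated [ProteinRecord-class] per data row. Cysteine positions are
#' computed from the `sequence` column when present, otherwise taken from
#' the explicit `cys_positions` column. Any malformed row raises an error
#' carrying its line number; nothing is silently dropped.
#'
#' @details Columns: `accession`, `gene_id`, `length`, `sequence`
#'   (optional), `cys_positions` (optional), `signal_peptide`,
#'   `topo_domains`, `disulfides`, `locations`. Feature strings are
#'   semicolon-separated within a cell, e.g. `"DISULFID 27..39"` or
#'   `"DISULFID 54..? /note=Interchain"`; `"?"` marks an unknown position
#'   (permitted only for disulfides). Coordinates are 1-based inclusive.
#'
#' @param file Path to a TSV file (ignored when `text` is given).
#' @param text Optional character scalar/vector holding the table literally.
#' @return A [ProteinSet-class].
#' @seealso [writeRecords()] for the inverse, [validateRecords()] for a
#'   per-row report instead of a first-error stop.
#' @export
parseRecords <- function(file, text = NULL) {
  df <- if (!is.null(text)) {
    utils::read.delim(text = paste(text, collapse = "\n"),
                      colClasses = "character", check.names = FALSE)
  } else {
    utils::read.delim(file, colClasses = "character", check.names = FALSE)
  }
  missingCols <- setdiff(setdiff(.DIALECT_COLUMNS, c("sequence", "cys_positions")),
                         names(df))
  if (length(missingCols))
    stop("missing required column(s): ", paste(missingCols, collapse = ", "))
  for (opt in c("sequence", "cys_positions"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_

  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    records[[i]] <- tryCatch(
      .parseRow(as.list(df[i, , drop = FALSE])),
      error = function(e) stop("row ", i, " (line ", i + 1L, "): ",
                               conditionMessage(e), call. = FALSE))
  }
  acc <- vapply(records, accession, character(1))
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  ProteinSet(records)
}

.formatSpan <- function(kind, a, b, note = NA_character_) {
  fmt <- function(x) if (is.na(x)) "?" else as.character(x)
  s <- paste0(kind, " ", fmt(a), "..", fmt(b))
  if (!is.na(note) && nzchar(note)) s <- paste0(s, " /note=", note)
  s
}

# placeholder sequence with C at the cysteine positions and A elsewhere:
# enough for sequence-derived cysteine parsing, deterministic by design
.synthSequence <- function(r) {
  chars <- rep("A", proteinLength(r))
  chars[cysteinePositions(r)] <- "C"
  paste(chars, collapse = "")
}

.recordToRow <- function(r, withSequence = FALSE) {
  ds <- disulfides(r)
  dsStr <- if (nrow(ds)) paste(vapply(seq_len(nrow(ds)), function(i) {
    .formatSpan("DISULFID", ds$cysA[i], ds$cysB[i],
                if (ds$interchain[i]) "Interchain" else NA_character_)
  }, character(1)), collapse = "; ") else ""
  td <- topoDomains(r)
  tdStr <- if (nrow(td)) paste(vapply(seq_len(nrow(td)), function(i) {
    .formatSpan("TOPO_DOM", td$start[i], td$end[i],
                if (nzchar(td$note[i])) td$note[i] else NA_character_)
  }, character(1)), collapse = "; ") else ""
  sp <- signalPeptide(r)
  data.frame(
    accession = accession(r),
    gene_id = geneId(r),
    length = proteinLength(r),
    sequence = if (withSequence) .synthSequence(r) else "",
    cys_positions = paste(cysteinePositions(r), collapse = ","),
    signal_peptide = if (length(sp)) .formatSpan("SIGNAL", sp[1], sp[2]) else "",
    topo_domains = tdStr,
    disulfides = dsStr,
    locations = paste(locations(r), collapse = "; "),
    stringsAsFactors = FALSE)
}

#' Write protein records to the annotation dialect
#'
#' Inverse of [parseRecords()]: `parseRecords(text = writeRecords(x))`
#' reproduces `x` field for field. Records are written in their current
#' order; output is byte-stable for a fixed input.
#'
#' @param records A [ProteinSet-class] or list of [ProteinRecord-class].
#' @param file Optional path; when `NULL` the TSV is returned as a
#'   character vector of lines.
#' @param withSequence Also emit a placeholder amino-acid sequence with
#'   `C` at the cysteine positions (for exercising sequence-derived
#'   parsing); default `FALSE`.
#' @return Invisibly the lines written, or the lines themselves when
#'   `file` is `NULL`.
#' @export
writeRecords <- function(records, file = NULL, withSequence = FALSE) {
  rows <- lapply(records, .recordToRow, withSequence = withSequence)
  df <- if (length(rows)) do.call(rbind, rows) else {
    as.data.frame(stats::setNames(rep(list(character(0)), length(.DIALECT_COLUMNS)),
                           .DIALECT_COLUMNS), stringsAsFactors = FALSE)
  }
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
  close(con)
  if (is.null(file)) return(out)
  writeLines(out, file, useBytes = TRUE)
  invisible(out)
}

#' Per-row validation report for an annotation table
#'
#' Like [parseRecords()] but collects every row's outcome instead of
#' stopping at the first error.
#'
#' @inheritParams parseRecords
#' @return data.frame with columns `row`, `line`, `accession`, `ok`,
#'   `message`.
#' @export
validateRecords <- function(file, text = NULL) {
  df <- if (!is.null(text)) {
    utils::read.delim(text = paste(text, collapse = "\n"),
                      colClasses = "character", check.names = FALSE)
  } else {
    utils::read.delim(file, colClasses = "character", check.names = FALSE)
  }
  for (opt in c("sequence", "cys_positions"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  out <- lapply(seq_len(nrow(df)), function(i) {
    res <- tryCatch({
      .parseRow(as.list(df[i, , drop = FALSE]))
      list(ok = TRUE, msg = "")
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    data.frame(row = i, line = i + 1L,
               accession = df$accession[i], ok = res$ok,
               message = res$msg, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  dup <- duplicated(df$accession)
  if (any(dup)) {
    rep$ok[dup] <- FALSE
    rep$message[dup] <- paste0("duplicate accession: ", df$accession[dup])
  }
  rep
}
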