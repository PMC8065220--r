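## Pulse-chase densitometry fractions.
##
## Band intensities are background-subtracted arbitrary units produced
## upstream by densitometry of autoradiographs; only the tabular
## arithmetic of the standard quantification conventions is implemented
## here. "Relative to the X-min time point" is interpreted as
## normalization by the total signal at that reference chase time, so
## loss or gain versus the reference stays visible.

.BANDS <- c("LYSATE", "SECRETED", "MONOMER", "DIMER", "ER_FORM",
            "GOLGI_FORM")

#' Validate a gel band-intensity table
#'
#' @param table data.frame with columns `condition`, `replicate`,
#'   `chase_min`, `band`, `intensity`.
#' @return The table, invisibly, after checking non-negative intensities,
#'   known band labels and uniqueness of `(condition, replicate,
#'   chase_min, band)`.
#' @export
validateBandTable <- function(table) {
  need <- c("condition", "replicate", "chase_min", "band", "intensity")
  if (!all(need %in% names(table)))
    stop("band table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table)) {
    if (!all(table$band %in% .BANDS))
      stop("unknown band label(s): ",
           paste(setdiff(unique(table$band), .BANDS), collapse = ", "))
    if (any(!is.finite(table$intensity)) || any(table$intensity < 0))
      stop("intensities must be non-negative finite values")
    if (any(table$chase_min < 0))
      stop("chase times must be non-negative")
    if (anyDuplicated(table[, c("condition", "replicate", "chase_min",
                                "band")]))
      stop("(condition, replicate, chase_min, band) must be unique")
  }
  invisible(table)
}

.bandIntensity <- function(table, condition, t, band, replicates) {
  vapply(replicates, function(rep) {
    v <- table$intensity[table$condition == condition &
                         table$replicate == rep &
                         table$chase_min == t & table$band == band]
    if (length(v) != 1L)
      stop("missing ", band, " intensity at t=", t, " min (", condition,
           ", replicate ", rep, ")")
    v
  }, numeric(1))
}

.kineticsFraction <- function(table, condition, t, numBand, denBands,
                              tDen, what) {
  validateBandTable(table)
  replicates <- sort(unique(table$replicate[table$condition == condition]))
  if (!length(replicates))
    stop("no replicates for condition '", condition, "'")
  num <- .bandIntensity(table, condition, t, numBand, replicates)
  den <- Reduce(`+`, lapply(denBands, function(b)
    .bandIntensity(table, condition, tDen, b, replicates)))
  if (any(den <= 0))
    stop("zero reference total for ", what, " (", condition,
         ", t_ref=", tDen, " min)")
  frac <- num / den
  names(frac) <- as.character(replicates)
  n <- length(frac)
  sdv <- if (n > 1) stats::sd(frac) else NA_real_
  structure(list(condition = condition, chaseMin = t,
                 replicates = frac, n = n,
                 fraction = mean(frac), sd = sdv,
                 sem = if (n > 1) sdv / sqrt(n) else NA_real_),
            class = "KineticsResult")
}

#' @export
print.KineticsResult <- function(x, ...) {
  cat(sprintf("KineticsResult: %s, %d min -> fraction %.4g", x$condition,
              x$chaseMin, x$fraction))
  if (x$n > 1) cat(sprintf(" +- %.3g SEM (n=%d)", x$sem, x$n))
  cat("\n")
  invisible(x)
}

#' Fraction of protein secreted at a chase time
#'
#' `SECRETED(t) / (SECRETED(t_ref) + LYSATE(t_ref))`, computed per
#' replicate and then summarized (mean, n-1 SD, SEM). The default
#' reference is the 15-min chase time point.
#'
#' @param table Band table (see [validateBandTable()]).
#' @param condition Condition label, e.g. `"21% O2"`.
#' @param t Chase time (min) at which to evaluate.
#' @param tRef Reference chase time whose total is the denominator.
#' @return A `KineticsResult` list: `condition`, `chaseMin`,
#'   per-`replicates` fractions, `n`, `fraction` (mean), `sd`, `sem`.
#' @export
fractionSecreted <- function(table, condition, t, tRef = 15) {
  .kineticsFraction(table, condition, t, "SECRETED",
                    c("SECRETED", "LYSATE"), tRef, "secretion")
}

#' Fraction of protein in the disulfide-linked dimer
#'
#' `DIMER(t) / (DIMER(t_ref) + MONOMER(t_ref))`; the default reference is
#' the 0-min chase time point. Dimer intensity is taken as-is (one label
#' count per band) unless `doubleDimer = TRUE`, which doubles the dimer
#' band to account for two labeled monomers per dimer.
#'
#' @inheritParams fractionSecreted
#' @param doubleDimer Double the dimer band intensity (default `FALSE`).
#' @return A `KineticsResult` (see [fractionSecreted()]).
#' @export
fractionDimer <- function(table, condition, t, tRef = 0,
                          doubleDimer = FALSE) {
  if (doubleDimer) {
    table <- validateBandTable(table)
    table$intensity[table$band == "DIMER"] <-
      2 * table$intensity[table$band == "DIMER"]
  }
  .kineticsFraction(table, condition, t, "DIMER", c("DIMER", "MONOMER"),
                    tRef, "dimerisation")
}

#' Fraction of protein in the Golgi-modified form
#'
#' `GOLGI_FORM(t) / (GOLGI_FORM(t) + ER_FORM(t))` - contemporaneous
#' same-lane normalization, no separate reference time point.
#'
#' @inheritParams fractionSecreted
#' @return A `KineticsResult` (see [fractionSecreted()]).
#' @export
fractionGolgi <- function(table, condition, t) {
  .kineticsFraction(table, condition, t, "GOLGI_FORM",
                    c("GOLGI_FORM", "ER_FORM"), t, "Golgi maturation")
}

#' Summarized kinetic curve over chase times
#'
#' @param table Band table.
#' @param mode `"secreted"`, `"dimer"` or `"golgi"`.
#' @param condition Condition label.
#' @param times Chase times to evaluate; default: all times present for
#'   the condition.
#' @param ... Passed to the underlying fraction function (`tRef`, ...).
#' @return data.frame with columns `condition`, `chase_min`, `fraction`,
#'   `sd`, `sem`, `n`.
#' @export
kineticsCurve <- function(table, mode = c("secreted", "dimer", "golgi"),
                          condition, times = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(times))
    times <- sort(unique(table$chase_min[table$condition == condition]))
  fn <- switch(mode, secreted = fractionSecreted, dimer = fractionDimer,
               golgi = fractionGolgi)
  rows <- lapply(times, function(t) {
    k <- fn(table, condition, t, ...)
    data.frame(condition = condition, chase_min = t,
               fraction = k$fraction, sd = k$sd, sem = k$sem, n = k$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Oxidative folding fitness
#'
#' Summary percentage locating a protein on the anoxia-vs-normoxia
#' maturation scale: `100 * fractionAnoxia / fractionNormoxia`, capped at
#' 100. The fractions are the terminal (longest assayed chase time)
#' maturation fractions in 0% and 21% oxygen. A zero normoxia fraction
#' leaves the fitness undefined (`NA`, with a warning).
#'
#' @param fractionAnoxia,fractionNormoxia Numeric vectors (recycled).
#' @return Percentages in `[0, 100]`, `NA` where undefined.
#' @examples
#' foldingFitness(c(0, 0.4), c(0.8, 0.8))  # 0, 50
#' @export
foldingFitness <- function(fractionAnoxia, fractionNormoxia) {
  out <- 100 * fractionAnoxia / fractionNormoxia
  bad <- !is.na(fractionNormoxia) & fractionNormoxia <= 0
  if (any(bad)) {
    warning("zero normoxia fraction: folding fitness undefined")
    out[bad] <- NA_real_
  }
  pmin(out, 100)
}
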