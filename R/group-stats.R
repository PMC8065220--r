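## Group summaries and two-group tests.

#' Summary statistics of one group
#'
#' @param x Numeric vector (NAs removed).
#' @return Named list: `n`, `mean`, `sem` (sample SD with n-1 denominator
#'   over sqrt(n)), `median`, `q25`, `q75`.
#' @export
groupSummary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = n, mean = mean(x),
       sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       median = q[2], q25 = q[1], q75 = q[3])
}

# Exact null distribution of the Mann-Whitney U statistic (tie-free):
# counts of arrangements with U_x = 0..n*m, via the standard recurrence
# N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1)
# (condition on whether the largest pooled value is an x or a y).
.uNullCounts <- function(n, m, cache = new.env(parent = emptyenv())) {
  key <- paste(n, m)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- if (n == 0L || m == 0L) 1 else {
    v1 <- c(rep(0, m), .uNullCounts(n - 1L, m, cache))   # largest is an x
    v2 <- .uNullCounts(n, m - 1L, cache)                 # largest is a y
    length(v1) <- length(v2) <- n * m + 1L
    v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
    v1 + v2
  }
  cache[[key]] <- res
  res
}

#' Mann-Whitney (Wilcoxon rank-sum) two-sample test
#'
#' Computes `U = min(U_x, U_y)` from midrank rank sums and a two-sided
#' p-value. When the pooled sample is tie-free and no larger than
#' `exactMax`, the p-value is exact (full enumeration of rank assignments
#' via the counting recurrence over the null distribution of U); otherwise
#' a normal approximation with tie-corrected variance and continuity
#' correction is used. When every pooled value coincides the comparison is
#' degenerate: `p = 1` with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @param exactMax Largest pooled size for the exact path (default 14,
#'   balancing runtime against fidelity).
#' @return Named list: `U`, `p`, `method` (`"EXACT"` or
#'   `"NORMAL_APPROX"`), `degenerate`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(x, y, exactMax = 14) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = nx * ny / 2, p = 1, method = "EXACT", degenerate = TRUE))
  r <- rank(pooled)
  Ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  Uy <- nx * ny - Ux
  U <- min(Ux, Uy)
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && nx + ny <= exactMax) {
    counts <- .uNullCounts(nx, ny)
    total <- sum(counts)
    lower <- sum(counts[seq_len(floor(U) + 1L)])         # P(U_x <= U)
    upper <- sum(counts[(nx * ny - floor(U) + 1L):(nx * ny + 1L)])
    p <- min(1, (lower + upper) / total)
    return(list(U = U, p = p, method = "EXACT", degenerate = FALSE))
  }
  N <- nx + ny
  tieTab <- table(pooled)
  tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tieCorr)
  if (sigma2 <= 0)
    return(list(U = U, p = 1, method = "NORMAL_APPROX", degenerate = TRUE))
  mu <- nx * ny / 2
  z <- (U - mu + 0.5) / sqrt(sigma2)  # U <= mu; continuity toward center
  p <- min(1, 2 * stats::pnorm(z))
  list(U = U, p = p, method = "NORMAL_APPROX", degenerate = FALSE)
}

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided, equal-variance t-test with `df = n_x + n_y - 2`. Zero pooled
#' variance is flagged degenerate: `p = 1` when the means agree, `p = 0`
#' (with `t = +-Inf`) when they differ.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Named list: `t`, `df`, `p`, `degenerate`.
#' @export
studentT <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(d) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tval <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       degenerate = FALSE)
}

.metricValues <- function(metrics, metric, cargoClass, group,
                          rangeComparison) {
  sel <- metrics$cargoClass == cargoClass & metrics$inductionGroup == group
  sub <- metrics[sel, , drop = FALSE]
  if (metric == "bondRange") {
    if (rangeComparison == "pooled")
      return(unlist(sub$bondRanges, use.names = FALSE))
    perProt <- vapply(sub$bondRanges, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1))
    return(perProt[!is.na(perProt)])
  }
  v <- sub[[metric]]
  if (metric == "fractionCysBonded") {
    nd <- sum(is.na(v))
    if (nd) message(nd, " protein(s) with no cysteines omitted from ",
                    "fraction comparison")
    v <- v[!is.na(v)]
  }
  v
}

#' Compare a disulfide metric between induction groups
#'
#' Runs the Fig-style induced-vs-noninduced contrast for one metric within
#' one cargo class: per-group summaries plus a two-sided Mann-Whitney test
#' on per-protein values. For `metric = "bondRange"` the pooled per-bond
#' values are compared by default (`rangeComparison = "pooled"`); the
#' per-protein mean range is available as an option. Proteins with an
#' undefined cysteine fraction are omitted from `"fractionCysBonded"`
#' comparisons.
#'
#' @param metrics data.frame from [metricsTable()].
#' @param metric One of `"bondsPer100aa"`, `"fractionCysBonded"`,
#'   `"bondRange"`, `"nFreeCys"`, `"D"`, `"I"`.
#' @param cargoClass `"SECRETED"` or `"MEMBRANE"`.
#' @param groups Two induction-group labels to compare.
#' @param rangeComparison `"pooled"` (per bond) or `"perProtein"`.
#' @param exactMax Passed to [mannWhitney()].
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(metrics, metric = "bondsPer100aa",
                          cargoClass = "SECRETED",
                          groups = c("INDUCED", "NONINDUCED"),
                          rangeComparison = c("pooled", "perProtein"),
                          exactMax = 14) {
  rangeComparison <- match.arg(rangeComparison)
  stopifnot(length(groups) == 2L)
  okMetrics <- c("bondsPer100aa", "fractionCysBonded", "bondRange",
                 "nFreeCys", "D", "I", "effectiveLength", "nCysteines")
  if (!metric %in% okMetrics)
    stop("unknown metric '", metric, "'")
  a <- .metricValues(metrics, metric, cargoClass, groups[1], rangeComparison)
  b <- .metricValues(metrics, metric, cargoClass, groups[2], rangeComparison)
  if (!length(a) || !length(b))
    stop("empty group in comparison of ", metric, " (", cargoClass, "): ",
         groups[1], " n=", length(a), ", ", groups[2], " n=", length(b))
  mw <- mannWhitney(a, b, exactMax = exactMax)
  new("GroupComparison", metric = metric, cargoClass = cargoClass,
      groupA = groups[1], groupB = groups[2],
      summaryA = groupSummary(a), summaryB = groupSummary(b),
      U = mw$U, p = mw$p, method = mw$method, degenerate = mw$degenerate)
}

#' All six standard contrasts
#'
#' Convenience wrapper running bonds per 100 aa, pooled bond range and
#' fraction of cysteines bonded for both cargo classes. No multiple-testing
#' correction is applied by default (raw p-values are reported); set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted p-values in an extra
#' column.
#'
#' @param metrics data.frame from [metricsTable()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @param ... Passed to [compareGroups()].
#' @return data.frame with one row per (cargo class, metric): group ns,
#'   means, SEMs, medians, IQRs, `U`, `p`, `method` (and `pAdjusted`).
#' @export
compareAllGroups <- function(metrics, adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  grid <- expand.grid(cargoClass = c("SECRETED", "MEMBRANE"),
                      metric = c("bondsPer100aa", "bondRange",
                                 "fractionCysBonded"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cmp <- compareGroups(metrics, grid$metric[i], grid$cargoClass[i], ...)
    sA <- cmp@summaryA; sB <- cmp@summaryB
    data.frame(cargoClass = grid$cargoClass[i], metric = grid$metric[i],
               nInduced = sA$n, nNoninduced = sB$n,
               meanInduced = sA$mean, semInduced = sA$sem,
               meanNoninduced = sB$mean, semNoninduced = sB$sem,
               medianInduced = sA$median, medianNoninduced = sB$median,
               U = cmp@U, p = cmp@p, method = cmp@method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$pAdjusted <- stats::p.adjust(out$p, "BH")
  out
}
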