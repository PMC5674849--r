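#' Division-rate exclusion filters
#'
#' Applies the two growth-based quality filters, in order:
#' 1. **Low growth** (plate-level, before replicate averaging): conditions
#'    whose untreated control underwent fewer than `minDivisions` divisions
#'    (default 0.3, a 23% increase in cell number) are excluded. When
#'    controls barely grow, GR values become highly variable and
#'    biologically meaningless. Flagged records (shrinking or non-growing
#'    controls) fall under this rule.
#' 2. **Slow division**: among the remainder, conditions whose nominal
#'    division time exceeds `maxDivisionTimeH` hours (default 80 h,
#'    corresponding to 0.9 divisions over a 72 h assay) are excluded; GR
#'    values from slow-growing cultures carry high replicate uncertainty.
#'
#' Both comparisons are strict ("fewer than", "greater than"), so boundary
#' records are retained. Each exclusion is attributed to the first rule
#' that fires, so the reported counts always sum to the input count.
#'
#' @param x a [GRTable].
#' @param minDivisions low-growth cutoff in control divisions (default 0.3).
#' @param maxDivisionTimeH slow-division cutoff in hours (default 80).
#' @return A list with `retained` (a filtered [GRTable]) and `report`
#'   (a [QCReport]).
#' @export
filterLowGrowth <- function(x, minDivisions = 0.3, maxDivisionTimeH = 80) {
  stopifnot(methods::is(x, "GRTable"),
            minDivisions > 0, maxDivisionTimeH > 0)
  d <- x@data
  low <- !is.finite(d$control_divisions) | d$control_divisions < minDivisions
  slow <- !low & d$division_time_h > maxDivisionTimeH
  keep <- !low & !slow

  byline <- function(mask) {
    t <- table(d$cell_line[mask])
    data.frame(cell_line = as.character(names(t) %||% character(0)),
               n = as.integer(t))
  }
  per_line <- merge(
    merge(stats::setNames(byline(low), c("cell_line", "n_low_growth")),
          stats::setNames(byline(slow), c("cell_line", "n_slow_division")),
          all = TRUE),
    stats::setNames(byline(keep), c("cell_line", "n_retained")), all = TRUE)
  if (nrow(per_line) > 0L)
    per_line[is.na(per_line)] <- 0L

  report <- methods::new("QCReport",
    nInput = nrow(d),
    nExcludedLowGrowth = sum(low),
    nExcludedSlowDivision = sum(slow),
    nRetained = sum(keep),
    perCellLine = per_line,
    semPercentiles = numeric(0),
    minDivisions = minDivisions,
    maxDivisionTimeH = maxDivisionTimeH)

  retained <- methods::new("GRTable", data = d[keep, , drop = FALSE],
                           assayDurationH = x@assayDurationH)
  list(retained = retained, report = report)
}

#' Average GR values across biological replicates
#'
#' Groups records by (cell line, perturbagen, concentration), averages the
#' GR value and the relative cell count across biological replicates, and
#' reports the SEM of the GR value (sample standard deviation / sqrt(n)).
#' The SEM is `NA` and `sem_defined = FALSE` for singleton groups.
#'
#' @param x a [GRTable] (normally the retained table from
#'   [filterLowGrowth()]).
#' @return data.frame with columns `cell_line`, `perturbagen`,
#'   `concentration`, `gr_value` (mean), `relative_count` (mean),
#'   `gr_sem`, `n_replicates`, `sem_defined`.
#' @export
averageReplicates <- function(x) {
  stopifnot(methods::is(x, "GRTable"))
  d <- x@data
  if (nrow(d) == 0L)
    return(data.frame(cell_line = character(0), perturbagen = character(0),
                      concentration = numeric(0), gr_value = numeric(0),
                      relative_count = numeric(0), gr_sem = numeric(0),
                      n_replicates = integer(0), sem_defined = logical(0)))
  key <- paste(d$cell_line, d$perturbagen, d$concentration, sep = "\r")
  groups <- split(seq_len(nrow(d)), key)
  rows <- lapply(groups, function(idx) {
    g <- d[idx, , drop = FALSE]
    n <- nrow(g)
    data.frame(cell_line = g$cell_line[1L], perturbagen = g$perturbagen[1L],
               concentration = g$concentration[1L],
               gr_value = mean(g$gr_value),
               relative_count = mean(g$relative_count),
               gr_sem = if (n >= 2L) stats::sd(g$gr_value) / sqrt(n)
                        else NA_real_,
               n_replicates = n,
               sem_defined = n >= 2L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_line, out$perturbagen, -out$concentration), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.SEM_PERCENTILES <- c(50, 75, 90, 95, 99)

.percentiles <- function(v, probs = .SEM_PERCENTILES) {
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    return(stats::setNames(rep(NA_real_, length(probs)),
                           paste0("p", probs)))
  stats::setNames(stats::quantile(v, probs / 100, names = FALSE, type = 7),
                  paste0("p", probs))
}

#' Replicate uncertainty as a function of the division cutoff
#'
#' For each candidate low-growth cutoff, applies the division filter to the
#' GR table, averages biological replicates, and reports the 50/75/90/95/99
#' percentiles of the SEM of the GR values among the retained conditions.
#' With `fitStatistics = TRUE` it additionally fits per-replicate
#' dose-response curves and reports percentiles of the sigmoid r-squared
#' and of the SEM of log10(GEC50) and log10(GR50) across replicates
#' (finite values only; the count of infinite GR50 values per group is
#' excluded from the SEM). This is the sweep used to justify a division
#' cutoff: replicate noise shrinks as faster-growing conditions are
#' required.
#'
#' @param x a [GRTable] with at least 2 biological replicates for a
#'   meaningful SEM.
#' @param cutoffs numeric vector of division cutoffs; a cutoff of 0
#'   reproduces the unfiltered percentiles.
#' @param fitStatistics also compute per-replicate fit statistics (slower).
#' @param options [grFitOptions()] for the per-replicate fits.
#' @return data.frame with one row per cutoff: `cutoff`, `n_retained`,
#'   `empty`, and columns `gr_sem_p50` ... `gr_sem_p99` (and, with
#'   `fitStatistics`, `r2_p*`, `log10_gec50_sem_p*`, `log10_gr50_sem_p*`).
#' @export
semVsCutoffSweep <- function(x, cutoffs = c(0, 0.3, 0.6, 0.9),
                             fitStatistics = FALSE,
                             options = grFitOptions()) {
  stopifnot(methods::is(x, "GRTable"))
  d <- x@data
  rows <- lapply(cutoffs, function(cut) {
    keep <- is.finite(d$control_divisions) & d$control_divisions >= cut &
      d$flag == "ok"
    sub <- methods::new("GRTable", data = d[keep, , drop = FALSE],
                        assayDurationH = x@assayDurationH)
    row <- data.frame(cutoff = cut, n_retained = sum(keep),
                      empty = sum(keep) == 0L)
    avg <- averageReplicates(sub)
    sems <- .percentiles(avg$gr_sem[avg$sem_defined])
    row <- cbind(row, as.data.frame(as.list(
      stats::setNames(sems, paste0("gr_sem_", names(sems))))))
    if (fitStatistics && sum(keep) > 0L) {
      fits <- .perReplicateFits(sub, options)
      row <- cbind(row,
        as.data.frame(as.list(stats::setNames(
          .percentiles(fits$r2), paste0("r2_", names(sems))))),
        as.data.frame(as.list(stats::setNames(
          .percentiles(fits$gec50_sem),
          paste0("log10_gec50_sem_", names(sems))))),
        as.data.frame(as.list(stats::setNames(
          .percentiles(fits$gr50_sem),
          paste0("log10_gr50_sem_", names(sems))))))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-replicate fits: r2 per fit; SEM of log10 GEC50 / log10 GR50 across
# replicates of a cell line/perturbagen pair, finite values only
.perReplicateFits <- function(x, options) {
  d <- x@data
  key <- paste(d$cell_line, d$perturbagen, d$replicate, sep = "\r")
  fits <- lapply(split(d, key), function(g) {
    if (length(unique(g$concentration)) < 4L) return(NULL)
    fit <- tryCatch(fitGRCurve(g$concentration, g$gr_value, options),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(cell_line = g$cell_line[1L], perturbagen = g$perturbagen[1L],
               r2 = fit@rSquared, gec50 = fit@gec50,
               gr50 = gr50FromFit(fit))
  })
  fits <- do.call(rbind, fits)
  if (is.null(fits) || nrow(fits) == 0L)
    return(list(r2 = numeric(0), gec50_sem = numeric(0),
                gr50_sem = numeric(0)))
  semlog <- function(v) {
    v <- log10(v[is.finite(v) & v > 0])
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  pair <- paste(fits$cell_line, fits$perturbagen, sep = "\r")
  list(r2 = fits$r2,
       gec50_sem = vapply(split(fits$gec50, pair), semlog, numeric(1)),
       gr50_sem = vapply(split(fits$gr50, pair), semlog, numeric(1)))
}
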