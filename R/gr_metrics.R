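#' GR50 from a fitted dose-response curve
#'
#' The primary potency metric: the concentration at which GR(c) = 0.5,
#' obtained in closed form from the sigmoid parameters,
#' GR50 = GEC50 * (0.5 / (0.5 - GRinf))^(1/hGR). Two censoring rules apply:
#' when GRinf is above 0.5 the curve never reaches 0.5 and GR50 is set to
#' +Inf; when the inverted value lies more than half an order of magnitude
#' (3.16-fold) above the highest tested concentration it is also set to
#' +Inf, to avoid extrapolation artefacts. For flat fits, GR50 is +Inf when
#' the flat level is above 0.5 and -Inf (below the tested range: the drug
#' is past its GR = 0.5 crossing at every tested dose) otherwise.
#'
#' @param fit a [GRFit].
#' @return GR50 in micromolar, possibly `Inf` or `-Inf`.
#' @examples
#' conc <- 33 / 5^(8:0)
#' fit <- fitGRCurve(conc, grSigmoid(conc, 0.4, 1, 1))
#' gr50FromFit(fit)   # 1 * (0.5/0.1)^1 = 5 uM
#' @export
gr50FromFit <- function(fit) {
  stopifnot(methods::is(fit, "GRFit"))
  if (fit@fitClass == "flat")
    return(if (fit@grInf > 0.5) Inf else -Inf)
  if (fit@grInf >= 0.5) return(Inf)
  gr50 <- fit@gec50 * (0.5 / (0.5 - fit@grInf))^(1 / fit@hGR)
  if (gr50 > fit@cMax * 10^0.5) return(Inf)
  gr50
}

#' GRmax: the GR value at the highest tested dose
#'
#' The primary efficacy metric: the (replicate-averaged) measured GR value
#' at the maximum tested concentration, clamped to \[-1, 1\] (values outside
#' that range can only arise from measurement noise) with an
#' `out_of_range` attribute flagging the clamp. Negative GRmax indicates a
#' cytotoxic response, 0 complete cytostasis, positive values partial
#' growth inhibition.
#'
#' @param concentration tested concentrations, micromolar.
#' @param gr GR values, same length; several values at the top dose are
#'   averaged.
#' @return GRmax, with attribute `out_of_range`.
#' @export
grMax <- function(concentration, gr) {
  stopifnot(length(concentration) == length(gr), length(gr) > 0L)
  v <- mean(gr[concentration == max(concentration)])
  clamped <- min(max(v, -1), 1)
  structure(clamped, out_of_range = (v < -1 || v > 1))
}

#' GRAOC: area over the GR dose-response curve
#'
#' The integrated drug effect across the tested range: the trapezoidal
#' integral of (1 - GR) over log10(concentration), normalized by the width
#' log10(c_max/c_min) of the range. A value of 0 means no effect at any
#' dose (GR identically 1); GR identically 0 (full cytostasis) gives 1;
#' cytotoxic responses push the value above 1. Computed from measured
#' (replicate-averaged) GR values, not the fitted curve, so it is robust to
#' fit failures.
#'
#' @param concentration tested concentrations, micromolar, at least 2
#'   distinct values, all > 0.
#' @param gr GR values, same length; duplicates per dose are averaged.
#' @return The normalized area over the curve.
#' @examples
#' grAOC(c(1, 10), c(1, 0.5))  # 0.25
#' @export
grAOC <- function(concentration, gr) {
  stopifnot(length(concentration) == length(gr))
  if (any(concentration <= 0)) stop("grAOC: concentrations must be positive")
  cu <- sort(unique(concentration))
  if (length(cu) < 2L)
    stop("grAOC: need at least 2 distinct concentrations")
  g <- vapply(cu, function(ci) mean(gr[concentration == ci]), numeric(1))
  lg <- log10(cu)
  pracma::trapz(lg, 1 - g) / (max(lg) - min(lg))
}

#' Assemble the GR metric record for one cell line / perturbagen pair
#'
#' Combines the measured points and the fitted curve into the six reported
#' metrics: GR50 and GRmax (potency and efficacy), GRAOC (integrated
#' effect), and the fit parameters GRinf, hGR and GEC50, together with the
#' tested range and fit diagnostics. GEC50 and hGR are `NA` for flat fits
#' (no half-maximal effect exists).
#'
#' @param concentration,gr the (replicate-averaged) measured points.
#' @param fit the [GRFit] produced from those points.
#' @param cell_line,perturbagen identity fields carried into the record.
#' @return One-row data.frame with columns `cell_line`, `perturbagen`,
#'   `gr50`, `gr_max`, `gr_aoc`, `gr_inf`, `h_gr`, `gec50`, `c_min`,
#'   `c_max`, `n_points`, `fit_class`, `r_squared`, `gr_max_clamped`,
#'   `gr50_note`.
#' @export
extractGRMetrics <- function(concentration, gr, fit,
                             cell_line = NA_character_,
                             perturbagen = NA_character_) {
  stopifnot(methods::is(fit, "GRFit"))
  gmax <- grMax(concentration, gr)
  gr50 <- gr50FromFit(fit)
  data.frame(
    cell_line = cell_line, perturbagen = perturbagen,
    gr50 = gr50,
    gr_max = as.numeric(gmax),
    gr_aoc = grAOC(concentration, gr),
    gr_inf = fit@grInf,
    h_gr = fit@hGR,
    gec50 = fit@gec50,
    c_min = fit@cMin, c_max = fit@cMax,
    n_points = fit@nPoints,
    fit_class = fit@fitClass,
    r_squared = fit@rSquared,
    gr_max_clamped = attr(gmax, "out_of_range"),
    gr50_note = if (is.infinite(gr50) && gr50 < 0) "below_range"
                else if (is.infinite(gr50)) "undefined" else "")
}

#' Compute GR metrics for every cell line / perturbagen pair
#'
#' Averages GR values across biological replicates per concentration,
#' fits the constrained sigmoid per (cell line, perturbagen) pair and
#' extracts the six metrics. Records whose tested concentration range
#' differs from the modal range of the table are flagged
#' (`range_differs`), because GRmax and GRAOC are only comparable across
#' records sharing the same dose range.
#'
#' @param x a [GRTable] (flagged non-`ok` records are dropped with a
#'   message) or a data.frame with columns `cell_line`, `perturbagen`,
#'   `concentration`, `gr_value` (already replicate-averaged or not).
#' @param options a [grFitOptions()] list.
#' @return A [GRMetrics] object.
#' @export
computeGRMetrics <- function(x, options = grFitOptions()) {
  if (methods::is(x, "GRTable")) {
    d <- x@data
    bad <- d$flag != "ok"
    if (any(bad)) {
      message("computeGRMetrics: dropping ", sum(bad),
              " flagged condition(s); run filterLowGrowth for full QC")
      d <- d[!bad, , drop = FALSE]
    }
  } else {
    d <- as.data.frame(x)
  }
  need <- c("cell_line", "perturbagen", "concentration", "gr_value")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L)
    stop("input missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(d) == 0L) return(methods::new("GRMetrics"))

  avg <- stats::aggregate(gr_value ~ cell_line + perturbagen + concentration,
                          data = d, FUN = mean)
  groups <- split(avg, paste(avg$cell_line, avg$perturbagen, sep = "\r"))
  rows <- lapply(groups, function(g) {
    fit <- fitGRCurve(g$concentration, g$gr_value, options)
    extractGRMetrics(g$concentration, g$gr_value, fit,
                     cell_line = g$cell_line[1L],
                     perturbagen = g$perturbagen[1L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  modal <- function(v) {
    u <- unique(v)
    u[which.max(tabulate(match(v, u)))]
  }
  out$range_differs <- out$c_min != modal(out$c_min) |
    out$c_max != modal(out$c_max)
  methods::new("GRMetrics", data = out[order(out$cell_line, out$perturbagen),
                                       , drop = FALSE])
}
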