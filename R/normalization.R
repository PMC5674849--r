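#' Robust average with log10 outlier rejection
#'
#' The robust average used to summarise technical replicate readouts: the
#' plain mean of the subset of values whose log10 distance from the log10 of
#' the plain mean of the full vector is strictly below `log10Threshold`,
#'
#'   mean(\{x_i in x : |log10(x_i) - log10(mean(x))| < t\}).
#'
#' The filter is a single pass against the mean of the full vector, not an
#' iterative trim. Treated technical triplicates use t = 1 (a tenfold
#' deviation); same-plate vehicle controls, of which there are more wells,
#' use t = 1.5. If the filter excludes every value (pathological spread) the
#' plain mean is returned with a warning.
#'
#' @param values numeric vector of positive values.
#' @param log10Threshold positive scalar, the strict log10 exclusion
#'   threshold.
#' @return The robust mean, a single number within `range(values)`.
#' @examples
#' robustMean(c(100, 110, 1), 1)    # the 1 is rejected: 105
#' robustMean(c(100, 110, 90), 1)   # nothing rejected: plain mean 100
#' @export
robustMean <- function(values, log10Threshold = 1) {
  if (length(values) == 0L) stop("robustMean: empty value vector")
  if (any(!is.finite(values) | values <= 0))
    stop("robustMean: all values must be positive and finite")
  if (!is.numeric(log10Threshold) || length(log10Threshold) != 1L ||
      log10Threshold <= 0)
    stop("robustMean: log10Threshold must be a positive scalar")
  m <- mean(values)
  keep <- abs(log10(values) - log10(m)) < log10Threshold
  if (!any(keep)) {
    warning("robustMean: all values rejected by the log10 filter; ",
            "falling back to the plain mean")
    return(m)
  }
  mean(values[keep])
}

#' Summarise corrected wells into per-condition robust averages
#'
#' Groups background-corrected wells into conditions and computes, for each
#' (cell line, perturbagen, concentration, biological replicate):
#' * `x_c`, the robust average ([robustMean()], threshold 1) of the treated
#'   technical-replicate wells;
#' * `x_ctrl`, the robust average (threshold 1.5) of all vehicle-control
#'   wells **from the same plate** -- conditions are never pooled across
#'   plates;
#' * `x_0`, the median of the corrected time-zero wells for that cell line
#'   and biological replicate (pooled across time-zero plates).
#'
#' @param x a background-corrected [PlateData].
#' @param treatedThreshold,controlThreshold log10 rejection thresholds for
#'   the treated and control robust averages.
#' @return data.frame with one row per condition: identity columns, `plate`,
#'   `x_c`, `x_ctrl`, `x_0`, `n_treated_used`, `n_ctrl_used`.
#' @export
summarizeConditions <- function(x, treatedThreshold = 1,
                                controlThreshold = 1.5) {
  stopifnot(methods::is(x, "PlateData"))
  if (!isTRUE(x@corrected))
    stop("summarizeConditions: PlateData must be background-corrected first ",
         "(see subtractBackground)")
  w <- x@wells
  treated <- w[w$role == "treated", , drop = FALSE]
  if (nrow(treated) == 0L)
    return(data.frame(cell_line = character(0), perturbagen = character(0),
                      concentration = numeric(0), replicate = character(0),
                      plate = character(0), x_c = numeric(0),
                      x_ctrl = numeric(0), x_0 = numeric(0),
                      n_treated_used = integer(0), n_ctrl_used = integer(0)))

  .nUsed <- function(values, threshold) {
    keep <- abs(log10(values) - log10(mean(values))) < threshold
    if (!any(keep)) length(values) else sum(keep)
  }

  ctrl <- w[w$role == "control", , drop = FALSE]
  ctrl_by_plate <- split(ctrl$corrected_value, ctrl$plate)
  t0 <- w[w$role == "time0", , drop = FALSE]
  t0_key <- paste(t0$cell_line, t0$replicate, sep = "\r")
  t0_by_group <- split(t0$corrected_value, t0_key)

  key <- paste(treated$cell_line, treated$perturbagen, treated$concentration,
               treated$replicate, treated$plate, sep = "\r")
  groups <- split(seq_len(nrow(treated)), key)
  rows <- lapply(groups, function(idx) {
    g <- treated[idx, , drop = FALSE]
    id <- g[1L, c("cell_line", "perturbagen", "concentration", "replicate",
                  "plate")]
    cvals <- ctrl_by_plate[[id$plate]]
    if (is.null(cvals) || length(cvals) == 0L)
      stop("no same-plate vehicle controls for condition: cell line '",
           id$cell_line, "', perturbagen '", id$perturbagen,
           "', concentration ", id$concentration, " uM, replicate '",
           id$replicate, "', plate '", id$plate, "'")
    t0vals <- t0_by_group[[paste(id$cell_line, id$replicate, sep = "\r")]]
    if (is.null(t0vals) || length(t0vals) == 0L)
      stop("no time-zero wells for cell line '", id$cell_line,
           "', replicate '", id$replicate, "'")
    data.frame(id,
               x_c = robustMean(g$corrected_value, treatedThreshold),
               x_ctrl = robustMean(cvals, controlThreshold),
               x_0 = stats::median(t0vals),
               n_treated_used = .nUsed(g$corrected_value, treatedThreshold),
               n_ctrl_used = .nUsed(cvals, controlThreshold))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_line, out$perturbagen, out$replicate,
                   -out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  out
}
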