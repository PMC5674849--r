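#' GR value from endpoint and time-zero cell counts
#'
#' The normalized growth rate inhibition value
#'
#'   GR(c) = 2^( log2(x(c)/x_0) / log2(x_ctrl/x_0) ) - 1,
#'
#' the per-division analogue of relative viability: the exponent is the
#' ratio k(c)/k(0) of the treated to untreated growth rates inferred from a
#' single endpoint and a time-zero count under exponential growth. GR = 1
#' means no drug effect, GR = 0 complete cytostasis, and negative values
#' cytotoxicity (net cell loss below the starting count). The value is
#' invariant to the readout units (any common rescaling of the three counts
#' cancels).
#'
#' @param x_c treated robust-average count(s), >= 1.
#' @param x_ctrl same-plate vehicle-control robust average, >= 1.
#' @param x_0 time-zero median count, >= 1.
#' @return GR value(s), vectorized over the inputs.
#' @examples
#' grValue(2000, 4000, 1000)  # half a division vs two: 2^(1/2) - 1
#' grValue(1000, 4000, 1000)  # back at the starting count: 0
#' @export
grValue <- function(x_c, x_ctrl, x_0) {
  if (any(x_c < 1 | x_ctrl < 1 | x_0 < 1))
    stop("grValue: counts must be >= 1 (background-corrected and clipped)")
  denom <- log2(x_ctrl / x_0)
  if (any(denom == 0))
    stop("grValue: x_ctrl equals x_0 (no control growth); ",
         "GR is undefined for this condition")
  2^(log2(x_c / x_0) / denom) - 1
}

#' Number of divisions of the untreated control
#'
#' log2(x_ctrl / x_0): how many population doublings the vehicle-control
#' culture underwent over the assay. May be zero or negative for
#' non-growing or shrinking controls; such values are passed through for the
#' QC layer to flag and exclude, not erased here.
#'
#' @param x_ctrl,x_0 control and time-zero counts, >= 1.
#' @return Division count(s), vectorized.
#' @examples
#' controlDivisions(2000, 1000)     # one doubling
#' controlDivisions(1231.14, 1000)  # 0.3 divisions = a 23% increase
#' @export
controlDivisions <- function(x_ctrl, x_0) {
  if (any(x_ctrl < 1 | x_0 < 1))
    stop("controlDivisions: counts must be >= 1")
  log2(x_ctrl / x_0)
}

#' Compute the GR table from condition summaries
#'
#' Turns the per-condition robust averages from [summarizeConditions()] into
#' GR records: relative cell count x(c)/x_ctrl, GR value, control division
#' count and nominal division time (assay duration / divisions; infinite
#' when the control did not grow). Degenerate conditions are flagged rather
#' than dropped -- `undefined_growth` when x_ctrl = x_0 (GR undefined) and
#' `shrinking_control` when x_ctrl < x_0 (GR computed but biologically
#' meaningless) -- so the QC filters can count them.
#'
#' @param summaries data.frame from [summarizeConditions()].
#' @param assayDurationH treatment window in hours (default 72).
#' @return A [GRTable].
#' @export
computeGRTable <- function(summaries, assayDurationH = 72) {
  stopifnot(is.data.frame(summaries), assayDurationH > 0)
  need <- c("cell_line", "perturbagen", "concentration", "replicate",
            "x_c", "x_ctrl", "x_0")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0L)
    stop("summaries missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- summaries
  if (nrow(d) == 0L) {
    empty <- data.frame(cell_line = character(0), perturbagen = character(0),
                        concentration = numeric(0), replicate = character(0),
                        plate = character(0), x_c = numeric(0),
                        x_ctrl = numeric(0), x_0 = numeric(0),
                        relative_count = numeric(0), gr_value = numeric(0),
                        control_divisions = numeric(0),
                        division_time_h = numeric(0), flag = character(0))
    return(methods::new("GRTable", data = empty,
                        assayDurationH = assayDurationH))
  }
  if (!"plate" %in% names(d)) d$plate <- NA_character_
  divisions <- controlDivisions(d$x_ctrl, d$x_0)
  gr <- rep(NA_real_, nrow(d))
  ok <- divisions != 0
  gr[ok] <- grValue(d$x_c[ok], d$x_ctrl[ok], d$x_0[ok])
  flag <- rep("ok", nrow(d))
  flag[divisions < 0] <- "shrinking_control"
  flag[divisions == 0] <- "undefined_growth"
  out <- data.frame(
    d[, c("cell_line", "perturbagen", "concentration", "replicate", "plate",
          "x_c", "x_ctrl", "x_0")],
    relative_count = d$x_c / d$x_ctrl,
    gr_value = gr,
    control_divisions = divisions,
    division_time_h = ifelse(divisions > 0, assayDurationH / divisions, Inf),
    flag = flag)
  rownames(out) <- NULL
  methods::new("GRTable", data = out, assayDurationH = assayDurationH)
}
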