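#' @import methods
NULL

.WELL_ROLES <- c("treated", "control", "time0", "blank")

.PLATE_COLUMNS <- c("cell_line", "perturbagen", "concentration", "role",
                    "replicate", "plate", "value")

#' PlateData: long-format well-level plate measurements
#'
#' Container for one-row-per-well plate data from an endpoint viability
#' screen. Each well carries its identity (cell line, perturbagen,
#' concentration in micromolar, biological replicate, plate) together with a
#' role -- `treated`, `control` (vehicle, concentration 0), `time0` (untreated
#' wells read at the moment of drug addition) or `blank` (medium only, no
#' cells) -- and the raw luminescence readout. After
#' [subtractBackground()] the table additionally carries `corrected_value`
#' (background-subtracted, floored at 1) and `was_clipped`.
#'
#' @slot wells data.frame with columns `cell_line`, `perturbagen`,
#'   `concentration`, `role`, `replicate`, `plate`, `value` and, once
#'   corrected, `corrected_value` and `was_clipped`.
#' @slot corrected logical scalar; `TRUE` after background subtraction.
#' @slot background named numeric vector of the background value applied per
#'   plate (empty until corrected).
#'
#' @seealso [readPlateTable()], [subtractBackground()], [summarizeConditions()]
#' @export
setClass("PlateData",
  representation(wells = "data.frame",
                 corrected = "logical",
                 background = "numeric"),
  prototype(wells = data.frame(), corrected = FALSE,
            background = numeric(0)))

setValidity("PlateData", function(object) {
  w <- object@wells
  msgs <- character(0)
  if (nrow(w) > 0L) {
    missing_cols <- setdiff(.PLATE_COLUMNS, names(w))
    if (length(missing_cols) > 0L)
      return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
    bad_role <- !w$role %in% .WELL_ROLES
    if (any(bad_role))
      msgs <- c(msgs, paste0("invalid role in row(s) ",
                             paste(which(bad_role), collapse = ", ")))
    bad_value <- !is.finite(w$value) | w$value < 0
    if (any(bad_value))
      msgs <- c(msgs, paste0("negative or non-finite readout value in row(s) ",
                             paste(which(bad_value), collapse = ", ")))
    treated <- w$role == "treated" & !bad_role
    bad_treated <- treated &
      (is.na(w$concentration) | w$concentration <= 0 |
         is.na(w$perturbagen) | !nzchar(w$perturbagen))
    if (any(bad_treated))
      msgs <- c(msgs, paste0(
        "treated well(s) must have concentration > 0 and a perturbagen: row(s) ",
        paste(which(bad_treated), collapse = ", ")))
    ctrl <- w$role == "control" & !bad_role
    bad_ctrl <- ctrl & (is.na(w$concentration) | w$concentration != 0)
    if (any(bad_ctrl))
      msgs <- c(msgs, paste0("control well(s) must have concentration 0: row(s) ",
                             paste(which(bad_ctrl), collapse = ", ")))
    if (isTRUE(object@corrected)) {
      if (!all(c("corrected_value", "was_clipped") %in% names(w))) {
        msgs <- c(msgs, "corrected PlateData must carry corrected_value and was_clipped")
      } else if (any(w$corrected_value < 1)) {
        msgs <- c(msgs, "corrected_value below the clipping floor of 1")
      }
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' GRTable: per-condition GR values and division statistics
#'
#' One row per (cell line, perturbagen, concentration, biological replicate)
#' condition, holding the robust-averaged counts, the relative cell count
#' x(c)/x_ctrl, the GR value, the number of divisions the untreated control
#' underwent (log2(x_ctrl/x_0)), the corresponding nominal division time in
#' hours, and a QC flag (`ok`, `shrinking_control` or `undefined_growth`).
#'
#' @slot data data.frame of GR records.
#' @slot assayDurationH numeric scalar, treatment window in hours.
#' @seealso [computeGRTable()], [filterLowGrowth()]
#' @export
setClass("GRTable",
  representation(data = "data.frame", assayDurationH = "numeric"),
  prototype(data = data.frame(), assayDurationH = 72))

setValidity("GRTable", function(object) {
  if (length(object@assayDurationH) != 1L || object@assayDurationH <= 0)
    return("assayDurationH must be a single positive number")
  d <- object@data
  if (nrow(d) > 0L) {
    need <- c("cell_line", "perturbagen", "concentration", "replicate",
              "relative_count", "gr_value", "control_divisions",
              "division_time_h", "flag")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols) > 0L)
      return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  TRUE
})

#' GRFit: a constrained sigmoidal GR dose-response fit
#'
#' Parameters of the model
#' GR(c) = GRinf + (1 - GRinf) / (1 + (c/GEC50)^hGR)
#' fitted by bounded least squares, or a flat (constant) fit when the
#' sigmoid is not statistically justified. Box constraints: GRinf in
#' \[-1, 1\], hGR in \[0.1, 5\], GEC50 within two orders of magnitude of the
#' tested concentration range. For flat fits `gec50` and `hGR` are `NA`.
#'
#' @slot grInf numeric, asymptotic GR value at infinite concentration.
#' @slot gec50 numeric, concentration (micromolar) of half-maximal effect.
#' @slot hGR numeric, Hill coefficient.
#' @slot fitClass character, `"sigmoid"` or `"flat"`.
#' @slot rSquared numeric, coefficient of determination against the mean-GR
#'   baseline (0 for flat fits; `NA` when the points have zero variance).
#' @slot pFlat numeric, p-value of the F-test comparing sigmoid vs constant
#'   model (`NA` when the test is disabled).
#' @slot cMin,cMax numeric, tested concentration range (micromolar).
#' @slot nPoints integer, number of fitted points.
#' @slot converged logical, optimizer convergence.
#' @seealso [fitGRCurve()], [grSigmoid()], [gr50FromFit()]
#' @export
setClass("GRFit",
  representation(grInf = "numeric", gec50 = "numeric", hGR = "numeric",
                 fitClass = "character", rSquared = "numeric",
                 pFlat = "numeric", cMin = "numeric", cMax = "numeric",
                 nPoints = "integer", converged = "logical"))

setValidity("GRFit", function(object) {
  msgs <- character(0)
  if (!object@fitClass %in% c("sigmoid", "flat"))
    msgs <- c(msgs, "fitClass must be 'sigmoid' or 'flat'")
  if (object@fitClass == "sigmoid") {
    if (object@hGR < 0.1 - 1e-9 || object@hGR > 5 + 1e-9)
      msgs <- c(msgs, "hGR outside [0.1, 5]")
    if (object@gec50 < object@cMin / 100 * (1 - 1e-9) ||
        object@gec50 > object@cMax * 100 * (1 + 1e-9))
      msgs <- c(msgs, "GEC50 outside two orders of magnitude of the tested range")
  }
  if (object@grInf < -1 - 1e-9 || object@grInf > 1 + 1e-9)
    msgs <- c(msgs, "grInf outside [-1, 1]")
  if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-9)
    msgs <- c(msgs, "rSquared above 1")
  if (length(msgs) == 0L) TRUE else msgs
})

#' GRMetrics: per cell line / perturbagen GR metric records
#'
#' One row per (cell line, perturbagen) pair with the six reported metrics
#' (GR50, GRmax, GRAOC, GRinf, hGR, GEC50), the tested concentration range,
#' fit class and goodness of fit, and edge-case flags. `gr50` is `Inf` when
#' undefined (GRinf above 0.5, or the inversion lands more than 3.16-fold
#' above the highest tested dose) and `-Inf` when a flat cytotoxic/cytostatic
#' fit places it below the tested range.
#'
#' @slot data data.frame of metric records.
#' @seealso [computeGRMetrics()], [extractGRMetrics()]
#' @export
setClass("GRMetrics", representation(data = "data.frame"),
         prototype(data = data.frame()))

setValidity("GRMetrics", function(object) {
  d <- object@data
  if (nrow(d) > 0L) {
    need <- c("cell_line", "perturbagen", "gr50", "gr_max", "gr_aoc",
              "gr_inf", "h_gr", "gec50", "c_min", "c_max", "fit_class",
              "r_squared")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols) > 0L)
      return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
    if (any(d$gr_max < -1 - 1e-9 | d$gr_max > 1 + 1e-9, na.rm = TRUE))
      return("gr_max outside [-1, 1]")
    bad50 <- is.finite(d$gr_inf) & d$gr_inf > 0.5 & is.finite(d$gr50)
    if (any(bad50, na.rm = TRUE))
      return("gr50 must be +Inf when gr_inf > 0.5")
  }
  TRUE
})

#' QCReport: bookkeeping of the division-rate exclusion filters
#'
#' Counts of conditions excluded by the low-growth filter (untreated control
#' underwent fewer than 0.3 divisions) and the slow-division filter
#' (division time above 80 h), attributed to the first rule that fires, plus
#' per-cell-line exclusion counts and, when available, percentiles of the
#' GR-value SEM across biological replicates.
#'
#' @slot nInput,nExcludedLowGrowth,nExcludedSlowDivision,nRetained integers.
#' @slot perCellLine data.frame of per-cell-line exclusion counts.
#' @slot semPercentiles named numeric, percentiles of GR-value SEM.
#' @slot minDivisions,maxDivisionTimeH numeric, the thresholds applied.
#' @seealso [filterLowGrowth()], [semVsCutoffSweep()]
#' @export
setClass("QCReport",
  representation(nInput = "integer", nExcludedLowGrowth = "integer",
                 nExcludedSlowDivision = "integer", nRetained = "integer",
                 perCellLine = "data.frame", semPercentiles = "numeric",
                 minDivisions = "numeric", maxDivisionTimeH = "numeric"))

setValidity("QCReport", function(object) {
  if (object@nInput !=
      object@nExcludedLowGrowth + object@nExcludedSlowDivision + object@nRetained)
    return("exclusion counts do not sum to the input count")
  TRUE
})

#' GRSimConfig: parameters of the synthetic plate simulator
#'
#' Describes the simulated screen: cell lines with their doubling times,
#' true GR dose-response parameters per cell line / perturbagen, a nine-point
#' 1:5 dilution series from a top concentration, assay duration, technical
#' and biological replication, seeding density, readout gain, additive
#' background luminescence and multiplicative (log-normal) readout noise.
#'
#' @slot cellLines data.frame with columns `cell_line`, `doubling_time_h`.
#' @slot truth data.frame with columns `cell_line`, `perturbagen`, `gr_inf`,
#'   `gec50`, `h_gr` (true curve parameters).
#' @slot doses numeric vector of treated concentrations, micromolar,
#'   strictly decreasing 1:5 series.
#' @slot assayDurationH numeric, treatment window (hours).
#' @slot techReps,bioReps integers.
#' @slot seedCells numeric, cells per well at time of treatment.
#' @slot gain numeric, luminescence units per cell.
#' @slot background numeric, additive background luminescence.
#' @slot noiseCV numeric, coefficient of variation of the multiplicative
#'   readout noise.
#' @slot nCtrlWells,nTime0Wells,nBlankWells integers, wells per plate.
#' @slot seed integer master seed.
#' @seealso [simulationConfig()], [simulatePlates()]
#' @export
setClass("GRSimConfig",
  representation(cellLines = "data.frame", truth = "data.frame",
                 doses = "numeric", assayDurationH = "numeric",
                 techReps = "integer", bioReps = "integer",
                 seedCells = "numeric", gain = "numeric",
                 background = "numeric", noiseCV = "numeric",
                 nCtrlWells = "integer", nTime0Wells = "integer",
                 nBlankWells = "integer", seed = "integer"))

setValidity("GRSimConfig", function(object) {
  msgs <- character(0)
  if (any(object@cellLines$doubling_time_h <= 0))
    msgs <- c(msgs, "doubling times must be positive")
  if (object@noiseCV < 0) msgs <- c(msgs, "noise CV must be >= 0")
  if (length(object@doses) < 2L || any(diff(object@doses) >= 0))
    msgs <- c(msgs, "doses must be strictly decreasing")
  if (any(object@doses <= 0)) msgs <- c(msgs, "doses must be positive")
  if (object@assayDurationH <= 0) msgs <- c(msgs, "assay duration must be positive")
  if (any(object@truth$gr_inf < -1))
    msgs <- c(msgs, "true gr_inf below -1 cannot be represented by the growth model")
  if (length(msgs) == 0L) TRUE else msgs
})
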