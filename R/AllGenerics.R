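#' Accessors for grscreen containers
#'
#' `wells()` returns the well-level data.frame of a [PlateData];
#' `isCorrected()` reports whether background subtraction has been applied;
#' `grValues()` returns the record data.frame of a [GRTable];
#' `assayDuration()` its treatment window in hours; `metrics()` the record
#' data.frame of a [GRMetrics]; `qcCounts()` the exclusion counts of a
#' [QCReport] as a named integer vector.
#'
#' @param x a grscreen container object.
#' @return A data.frame (or, for `isCorrected`/`assayDuration`/`qcCounts`,
#'   an atomic vector) -- see the per-accessor description.
#' @name accessors
#' @aliases wells isCorrected grValues assayDuration metrics qcCounts
NULL

#' @rdname accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname accessors
#' @export
setGeneric("isCorrected", function(x) standardGeneric("isCorrected"))

#' @rdname accessors
#' @export
setGeneric("grValues", function(x) standardGeneric("grValues"))

#' @rdname accessors
#' @export
setGeneric("assayDuration", function(x) standardGeneric("assayDuration"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setGeneric("qcCounts", function(x) standardGeneric("qcCounts"))

#' @rdname accessors
#' @export
setMethod("wells", "PlateData", function(x) x@wells)

#' @rdname accessors
#' @export
setMethod("isCorrected", "PlateData", function(x) x@corrected)

#' @rdname accessors
#' @export
setMethod("grValues", "GRTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("assayDuration", "GRTable", function(x) x@assayDurationH)

#' @rdname accessors
#' @export
setMethod("metrics", "GRMetrics", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("qcCounts", "QCReport", function(x) {
  c(n_input = x@nInput,
    n_excluded_low_growth = x@nExcludedLowGrowth,
    n_excluded_slow_division = x@nExcludedSlowDivision,
    n_retained = x@nRetained)
})

setMethod("show", "PlateData", function(object) {
  w <- object@wells
  cat("PlateData with", nrow(w), "wells on",
      length(unique(w$plate)), "plate(s)\n")
  if (nrow(w) > 0L) {
    cat("  roles:", paste(sprintf("%s=%d", names(table(w$role)),
                                  table(w$role)), collapse = ", "), "\n")
    cat("  cell lines:", length(unique(w$cell_line[w$role != "blank"])),
        " perturbagens:",
        length(unique(w$perturbagen[w$role == "treated"])), "\n")
  }
  cat("  background-corrected:", object@corrected, "\n")
})

setMethod("show", "GRTable", function(object) {
  d <- object@data
  cat("GRTable with", nrow(d), "condition(s);",
      "assay duration", object@assayDurationH, "h\n")
  if (nrow(d) > 0L) {
    cat("  cell lines:", length(unique(d$cell_line)),
        " perturbagens:", length(unique(d$perturbagen)), "\n")
    flg <- table(d$flag)
    cat("  flags:", paste(sprintf("%s=%d", names(flg), flg), collapse = ", "),
        "\n")
    cat("  GR value range:",
        sprintf("[%.3f, %.3f]", min(d$gr_value, na.rm = TRUE),
                max(d$gr_value, na.rm = TRUE)), "\n")
  }
})

setMethod("show", "GRFit", function(object) {
  cat("GRFit (", object@fitClass, ") on ", object@nPoints, " points, ",
      sprintf("range [%.4g, %.4g] uM\n", object@cMin, object@cMax), sep = "")
  if (object@fitClass == "sigmoid") {
    cat(sprintf("  GRinf = %.4f, GEC50 = %.4g uM, hGR = %.3f, r2 = %.4f\n",
                object@grInf, object@gec50, object@hGR, object@rSquared))
  } else {
    cat(sprintf("  flat at GR = %.4f\n", object@grInf))
  }
})

setMethod("show", "GRMetrics", function(object) {
  d <- object@data
  cat("GRMetrics with", nrow(d), "cell line/perturbagen pair(s)\n")
  if (nrow(d) > 0L) {
    cat("  fit classes:",
        paste(sprintf("%s=%d", names(table(d$fit_class)), table(d$fit_class)),
              collapse = ", "), "\n")
    cat("  GR50 undefined (+Inf):", sum(is.infinite(d$gr50) & d$gr50 > 0), "\n")
  }
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nInput, "conditions in;",
      object@nRetained, "retained\n")
  cat("  excluded, control divisions <", object@minDivisions, ":",
      object@nExcludedLowGrowth, "\n")
  cat("  excluded, division time >", object@maxDivisionTimeH, "h:",
      object@nExcludedSlowDivision, "\n")
  if (length(object@semPercentiles) > 0L) {
    cat("  GR SEM percentiles:\n")
    print(round(object@semPercentiles, 4))
  }
})

setMethod("show", "GRSimConfig", function(object) {
  cat("GRSimConfig:", nrow(object@cellLines), "cell line(s),",
      length(unique(object@truth$perturbagen)), "perturbagen(s),",
      length(object@doses), "doses",
      sprintf("[%.4g, %.4g] uM\n", min(object@doses), max(object@doses)))
  cat("  ", object@techReps, "technical x", object@bioReps,
      "biological replicates;", object@assayDurationH, "h assay;",
      "noise CV", object@noiseCV, "; seed", object@seed, "\n")
})
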