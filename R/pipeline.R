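#' Run the full GR pipeline on a raw plate table
#'
#' Composes the stages end to end: background correction, robust
#' per-condition averaging, GR values, division-rate QC filtering,
#' replicate averaging, dose-response fitting with metric extraction, and
#' per-perturbagen (and, with annotations, per-class) aggregation. When
#' `outputDir` is given, the intermediate and final tables are written as
#' CSV (GR table, QC report counts, metrics table, aggregates).
#'
#' @param x a raw [PlateData] or a path to a plate CSV.
#' @param schema column mapping for reading, see [plateSchema()].
#' @param background background policy, see [subtractBackground()].
#' @param assayDurationH treatment window, hours (default 72).
#' @param minDivisions,maxDivisionTimeH QC thresholds, see
#'   [filterLowGrowth()].
#' @param fitOptions a [grFitOptions()] list.
#' @param annotations optional drug-class annotation data.frame or CSV
#'   path, see [readClassAnnotations()].
#' @param outputDir optional directory for CSV outputs.
#' @param verbose print QC exclusion counts (default TRUE).
#' @return A list with `grTable` ([GRTable], unfiltered), `qc`
#'   ([QCReport]), `retained` ([GRTable]), `averaged` (data.frame),
#'   `metrics` ([GRMetrics]), `byPerturbagen` and (if annotated) `byClass`
#'   aggregate data.frames.
#' @export
runGRPipeline <- function(x, schema = plateSchema(),
                          background = "from_blanks",
                          assayDurationH = 72,
                          minDivisions = 0.3, maxDivisionTimeH = 80,
                          fitOptions = grFitOptions(),
                          annotations = NULL, outputDir = NULL,
                          verbose = TRUE) {
  if (is.character(x)) x <- readPlateTable(x, schema)
  stopifnot(methods::is(x, "PlateData"))
  if (is.character(annotations)) annotations <- readClassAnnotations(annotations)

  corrected <- subtractBackground(x, background)
  summaries <- summarizeConditions(corrected)
  gr_table <- computeGRTable(summaries, assayDurationH)
  qc <- filterLowGrowth(gr_table, minDivisions, maxDivisionTimeH)
  if (verbose) {
    counts <- qcCounts(qc$report)
    message(sprintf(
      "QC: %d conditions in; %d excluded (low growth), %d excluded (slow division), %d retained",
      counts[["n_input"]], counts[["n_excluded_low_growth"]],
      counts[["n_excluded_slow_division"]], counts[["n_retained"]]))
  }
  averaged <- averageReplicates(qc$retained)
  mets <- computeGRMetrics(averaged, fitOptions)
  if (nrow(metrics(mets)) > 0L) {
    by_pert <- aggregateMetrics(mets, by = "perturbagen")
    by_class <- if (!is.null(annotations))
      aggregateMetrics(mets, annotations, by = "drug_class") else NULL
  } else {
    if (verbose) message("no conditions survived QC; no metrics to aggregate")
    by_pert <- NULL
    by_class <- NULL
  }

  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    writeGRTable(gr_table, file.path(outputDir, "gr_values.csv"))
    writeGRTable(qc$retained, file.path(outputDir, "gr_values_retained.csv"))
    utils::write.csv(as.data.frame(as.list(qcCounts(qc$report))),
                     file.path(outputDir, "qc_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$report@perCellLine,
                     file.path(outputDir, "qc_per_cell_line.csv"),
                     row.names = FALSE)
    writeGRMetrics(mets, file.path(outputDir, "gr_metrics.csv"))
    if (!is.null(by_pert))
      utils::write.csv(by_pert,
                       file.path(outputDir, "aggregate_by_perturbagen.csv"),
                       row.names = FALSE)
    if (!is.null(by_class))
      utils::write.csv(by_class, file.path(outputDir, "aggregate_by_class.csv"),
                       row.names = FALSE)
  }
  list(grTable = gr_table, qc = qc$report, retained = qc$retained,
       averaged = averaged, metrics = mets, byPerturbagen = by_pert,
       byClass = by_class)
}
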