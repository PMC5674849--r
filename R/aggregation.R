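#' Read a perturbagen drug-class annotation table
#'
#' CSV with columns `perturbagen` and `drug_class` (e.g. TUBB, Proteasome,
#' MAPK, HDAC). Perturbagens without an annotation are assigned class
#' `"N/A"` downstream.
#'
#' @param path CSV path.
#' @return data.frame with columns `perturbagen`, `drug_class`.
#' @export
readClassAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("perturbagen", "drug_class"), names(df))
  if (length(missing_cols) > 0L)
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$perturbagen))
    stop("annotation table maps a perturbagen to more than one class")
  df[, c("perturbagen", "drug_class")]
}

.AGG_METRICS <- c("gr50", "gr_max", "gr_aoc", "gr_inf", "h_gr", "gec50")
.LOG_METRICS <- c("gr50", "gec50")

# type-7 quantiles; concentration-scale metrics are summarised in log10
# space (infinities ride along: +Inf sorts last, -Inf first) and
# back-transformed to micromolar
.metricQuantiles <- function(v, metric) {
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    return(c(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
  if (metric %in% .LOG_METRICS) {
    q <- stats::quantile(log10(v), c(0.5, 0.25, 0.75), names = FALSE,
                         type = 7)
    q <- 10^q
  } else {
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  }
  c(median = q[1L], q25 = q[2L], q75 = q[3L])
}

#' Aggregate GR metrics per perturbagen or per drug class
#'
#' Summarises the per-cell-line metric records into median and quartiles of
#' each metric per perturbagen, or per drug class using an annotation table.
#' Concentration-scale metrics (GR50, GEC50) are summarised on the log10
#' scale and reported back in micromolar; infinite GR50 values (resistant
#' lines) are retained and sort above every finite concentration, so they
#' are not silently dropped from the quantiles. Quantiles use linear
#' interpolation (type 7).
#'
#' @param x a [GRMetrics] object.
#' @param annotations optional data.frame from [readClassAnnotations()];
#'   required when `by = "drug_class"`; perturbagens missing from it get
#'   class `"N/A"`.
#' @param by `"perturbagen"` (default) or `"drug_class"`.
#' @return data.frame with one row per group x metric: `group`, `metric`,
#'   `median`, `q25`, `q75`, `n_cell_lines`.
#' @export
aggregateMetrics <- function(x, annotations = NULL,
                             by = c("perturbagen", "drug_class")) {
  stopifnot(methods::is(x, "GRMetrics"))
  by <- match.arg(by)
  d <- x@data
  if (nrow(d) == 0L) stop("aggregateMetrics: no metric records")
  if (by == "drug_class") {
    if (is.null(annotations))
      d$drug_class <- "N/A"
    else {
      d <- merge(d, annotations, by = "perturbagen", all.x = TRUE)
      d$drug_class[is.na(d$drug_class)] <- "N/A"
    }
  }
  groups <- split(d, d[[by]])
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (nrow(g) == 0L) {
      warning("aggregateMetrics: empty group '", gname, "' omitted")
      return(NULL)
    }
    do.call(rbind, lapply(.AGG_METRICS, function(m) {
      q <- .metricQuantiles(g[[m]], m)
      data.frame(group = gname, metric = m, median = q[["median"]],
                 q25 = q[["q25"]], q75 = q[["q75"]],
                 n_cell_lines = length(unique(g$cell_line)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a response by potency and efficacy
#'
#' Four response classes from the two headline metrics: potency from GR50
#' below/above 1 uM and efficacy from the sign of GRmax (negative =
#' cytotoxic, the drug kills cells; non-negative = cytostatic, the drug at
#' most arrests growth). GR50 exactly at the threshold counts as potent.
#'
#' @param gr50 GR50 value(s), micromolar, may be `Inf`/`-Inf`.
#' @param grMax GRmax value(s).
#' @param potencyThreshold potency boundary, micromolar (default 1).
#' @param efficacyThreshold efficacy boundary on GRmax (default 0).
#' @return character vector: `"potent-cytotoxic"`, `"potent-cytostatic"`,
#'   `"weak-cytotoxic"` or `"weak-cytostatic"`.
#' @examples
#' classifyResponse(0.1, -0.3)   # potent-cytotoxic
#' classifyResponse(Inf, 0.6)    # weak-cytostatic
#' @export
classifyResponse <- function(gr50, grMax, potencyThreshold = 1,
                             efficacyThreshold = 0) {
  stopifnot(length(gr50) == length(grMax))
  potent <- ifelse(gr50 <= potencyThreshold, "potent", "weak")
  toxic <- ifelse(grMax < efficacyThreshold, "cytotoxic", "cytostatic")
  paste(potent, toxic, sep = "-")
}
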