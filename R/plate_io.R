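#' Default column-name mapping for plate tables
#'
#' Maps the internal field names onto the column headers expected in input
#' CSV files. Override individual entries to match your plate-reader export,
#' e.g. `plateSchema(value = "luminescence")`.
#'
#' @param cell_line,perturbagen,concentration,role,replicate,plate,value
#'   column names in the file.
#' @return Named character vector mapping internal names to file columns.
#' @examples
#' plateSchema()
#' plateSchema(perturbagen = "drug", value = "CTG")
#' @export
plateSchema <- function(cell_line = "cell_line", perturbagen = "agent",
                        concentration = "concentration", role = "role",
                        replicate = "replicate", plate = "plate",
                        value = "value") {
  c(cell_line = cell_line, perturbagen = perturbagen,
    concentration = concentration, role = role, replicate = replicate,
    plate = plate, value = value)
}

.coerceWells <- function(df) {
  df$cell_line <- as.character(df$cell_line)
  df$perturbagen <- as.character(df$perturbagen)
  df$perturbagen[is.na(df$perturbagen)] <- ""
  df$role <- as.character(df$role)
  df$replicate <- as.character(df$replicate)
  df$plate <- as.character(df$plate)
  df
}

#' Read a long-format plate table
#'
#' Reads a CSV with one row per well into a [PlateData] object, validating
#' roles, readout values and the treated/control concentration rules. Rows
#' whose numeric fields cannot be parsed are reported in the error message
#' rather than silently dropped. Concentrations are in micromolar;
#' concentration may be empty for `time0` and `blank` wells.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector from [plateSchema()] mapping internal
#'   field names to file column names.
#' @return A [PlateData] object (not background-corrected).
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' df <- data.frame(cell_line = "L1", agent = c("drugA", "", ""),
#'                  concentration = c(1, 0, NA),
#'                  role = c("treated", "control", "time0"),
#'                  replicate = 1, plate = "P1", value = c(400, 900, 250))
#' write.csv(df, tmp, row.names = FALSE)
#' pd <- readPlateTable(tmp)
#' nrow(wells(pd))
#' @export
readPlateTable <- function(path, schema = plateSchema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L)
    stop("plate table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- raw[unname(schema)]
  names(df) <- names(schema)

  conc <- suppressWarnings(as.numeric(df$concentration))
  bad_conc <- which(!is.na(df$concentration) & nzchar(df$concentration) &
                      is.na(conc))
  val <- suppressWarnings(as.numeric(df$value))
  bad_val <- which(is.na(val) | !nzchar(df$value))
  if (length(bad_conc) > 0L || length(bad_val) > 0L)
    stop("unparseable numeric value(s) in row(s): ",
         paste(sort(unique(c(bad_conc, bad_val))), collapse = ", "))
  neg <- which(val < 0)
  if (length(neg) > 0L)
    stop("negative readout value in row(s): ", paste(neg, collapse = ", "))
  df$concentration <- conc
  df$value <- val
  df <- .coerceWells(df)
  methods::new("PlateData", wells = df, corrected = FALSE)
}

#' Write a plate table or result table to CSV
#'
#' `writePlateTable()` writes a [PlateData] back to the long CSV dialect
#' [readPlateTable()] reads (round-trip safe). `writeGRTable()` and
#' `writeGRMetrics()` write the GR-value and metrics tables; infinite GR50
#' values are serialized as `Inf`/`-Inf`.
#'
#' @param x the object to write.
#' @param path output CSV path.
#' @param schema column mapping used to name the output header (PlateData
#'   only).
#' @return Invisibly, the path written.
#' @export
writePlateTable <- function(x, path, schema = plateSchema()) {
  stopifnot(methods::is(x, "PlateData"))
  df <- x@wells[, .PLATE_COLUMNS]
  names(df) <- unname(schema[.PLATE_COLUMNS])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname writePlateTable
#' @export
writeGRTable <- function(x, path) {
  stopifnot(methods::is(x, "GRTable"))
  utils::write.csv(x@data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writePlateTable
#' @export
writeGRMetrics <- function(x, path) {
  stopifnot(methods::is(x, "GRMetrics"))
  utils::write.csv(x@data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Background-correct raw well readouts
#'
#' Subtracts the background luminescence (wells with medium but no cells)
#' from every non-blank well and floors the result at 1: corrected values
#' below 1 or negative arise from near-background readouts and are set to 1,
#' with `was_clipped` recording which wells were floored. Blank wells are
#' consumed to estimate the background and excluded from the output.
#'
#' @param x a [PlateData] of raw readouts.
#' @param background either `"from_blanks"` (default; per-plate median of the
#'   blank wells on that plate), a single non-negative number applied to all
#'   plates, or a named numeric vector of per-plate backgrounds.
#' @return A background-corrected [PlateData] whose wells carry
#'   `corrected_value` (>= 1) and `was_clipped`.
#' @examples
#' df <- data.frame(cell_line = "L1", perturbagen = "",
#'                  concentration = NA_real_, role = c("time0", "blank"),
#'                  replicate = "1", plate = "P1", value = c(500, 100))
#' pd <- methods::new("PlateData", wells = df)
#' cw <- subtractBackground(pd)
#' wells(cw)$corrected_value   # 400
#' @export
subtractBackground <- function(x, background = "from_blanks") {
  stopifnot(methods::is(x, "PlateData"))
  w <- x@wells
  plates <- unique(w$plate)
  if (identical(background, "from_blanks")) {
    bg <- vapply(plates, function(p) {
      b <- w$value[w$plate == p & w$role == "blank"]
      if (length(b) == 0L)
        stop("plate '", p, "' has no blank wells and no explicit background ",
             "was supplied")
      stats::median(b)
    }, numeric(1))
  } else if (is.numeric(background) && length(background) == 1L &&
             is.null(names(background))) {
    if (background < 0) stop("background must be >= 0")
    bg <- stats::setNames(rep(background, length(plates)), plates)
  } else if (is.numeric(background) && !is.null(names(background))) {
    missing_pl <- setdiff(plates[plates %in% w$plate[w$role != "blank"]],
                          names(background))
    if (length(missing_pl) > 0L)
      stop("no background supplied for plate(s): ",
           paste(missing_pl, collapse = ", "))
    if (any(background < 0)) stop("background must be >= 0")
    bg <- background
  } else {
    stop("background must be \"from_blanks\", a single number, ",
         "or a named per-plate numeric vector")
  }
  out <- w[w$role != "blank", , drop = FALSE]
  raw_minus_bg <- out$value - unname(bg[out$plate])
  out$corrected_value <- pmax(raw_minus_bg, 1)
  out$was_clipped <- raw_minus_bg < 1
  rownames(out) <- NULL
  methods::new("PlateData", wells = out, corrected = TRUE, background = bg)
}
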