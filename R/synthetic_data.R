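#' Build a synthetic screen configuration
#'
#' Describes a simulated endpoint viability screen matching the real assay
#' layout: nine-dose 1:5 dilution series, 72 h treatment, technical
#' triplicates, biological duplicates, additive background luminescence and
#' multiplicative log-normal readout noise. Cells grow exponentially at a
#' per-line doubling time; drug shifts the growth rate according to the
#' true GR curve, so the simulator inverts GR(c) = 2^(k(c)/k(0)) - 1 to
#' get the treated rate k(c) = k(0) * log2(GR_true(c) + 1).
#'
#' @param cellLines data.frame with columns `cell_line`,
#'   `doubling_time_h`, or a named numeric vector of doubling times.
#' @param truth data.frame of true curve parameters with columns
#'   `perturbagen`, `gr_inf`, `gec50`, `h_gr` and optionally `cell_line`;
#'   without a `cell_line` column each perturbagen row is crossed with
#'   every cell line.
#' @param topConcentration top dose, micromolar; the realistic screening
#'   range puts it between 33 and 167 (default 100).
#' @param nDoses,dilution dilution series: `nDoses` doses descending by
#'   `1/dilution` (default nine-point 1:5).
#' @param assayDurationH treatment window, hours (default 72).
#' @param techReps,bioReps technical wells per condition (default 3) and
#'   biological replicates (default 2).
#' @param seedCells cells per well at the time of treatment (default 1000).
#' @param gain luminescence units per cell (default 1; GR is unit
#'   invariant, so this only scales readouts).
#' @param background additive background luminescence from medium-only
#'   wells; realistic values run 35-250 (default 100).
#' @param noiseCV coefficient of variation of the multiplicative
#'   (log-normal) readout noise (default 0.05).
#' @param nCtrlWells,nTime0Wells,nBlankWells vehicle-control, time-zero and
#'   blank wells per plate.
#' @param seed master seed; per-plate streams are derived from it.
#' @return A [GRSimConfig].
#' @examples
#' cfg <- simulationConfig(
#'   cellLines = c(FAST = 24, SLOW = 60),
#'   truth = data.frame(perturbagen = "drugA", gr_inf = 0.1,
#'                      gec50 = 0.5, h_gr = 2))
#' cfg
#' @export
simulationConfig <- function(cellLines,
                             truth,
                             topConcentration = 100,
                             nDoses = 9L, dilution = 5,
                             assayDurationH = 72,
                             techReps = 3L, bioReps = 2L,
                             seedCells = 1000, gain = 1,
                             background = 100, noiseCV = 0.05,
                             nCtrlWells = 6L, nTime0Wells = 6L,
                             nBlankWells = 4L, seed = 1L) {
  if (is.numeric(cellLines) && !is.null(names(cellLines)))
    cellLines <- data.frame(cell_line = names(cellLines),
                            doubling_time_h = unname(cellLines))
  stopifnot(is.data.frame(cellLines),
            all(c("cell_line", "doubling_time_h") %in% names(cellLines)))
  stopifnot(is.data.frame(truth),
            all(c("perturbagen", "gr_inf", "gec50", "h_gr") %in% names(truth)))
  if (!"cell_line" %in% names(truth)) {
    truth <- merge(data.frame(cell_line = cellLines$cell_line), truth)
  }
  doses <- topConcentration / dilution^(0:(nDoses - 1L))
  methods::new("GRSimConfig",
    cellLines = cellLines, truth = truth, doses = doses,
    assayDurationH = assayDurationH, techReps = as.integer(techReps),
    bioReps = as.integer(bioReps), seedCells = seedCells, gain = gain,
    background = background, noiseCV = noiseCV,
    nCtrlWells = as.integer(nCtrlWells),
    nTime0Wells = as.integer(nTime0Wells),
    nBlankWells = as.integer(nBlankWells), seed = as.integer(seed))
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [GRSimConfig].
#' @return `readSimulationConfig` returns a [GRSimConfig];
#'   `writeSimulationConfig` invisibly returns the path.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simulationConfig(
    cellLines = as.data.frame(y$cell_lines),
    truth = as.data.frame(y$truth),
    topConcentration = y$top_concentration %||% 100,
    nDoses = y$n_doses %||% 9L, dilution = y$dilution %||% 5,
    assayDurationH = y$assay_duration_h %||% 72,
    techReps = y$tech_reps %||% 3L, bioReps = y$bio_reps %||% 2L,
    seedCells = y$seed_cells %||% 1000, gain = y$gain %||% 1,
    background = y$background %||% 100, noiseCV = y$noise_cv %||% 0.05,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readSimulationConfig
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(methods::is(config, "GRSimConfig"))
  yaml::write_yaml(list(
    cell_lines = as.list(config@cellLines),
    truth = as.list(config@truth),
    top_concentration = max(config@doses),
    n_doses = length(config@doses),
    dilution = config@doses[1L] / config@doses[2L],
    assay_duration_h = config@assayDurationH,
    tech_reps = config@techReps, bio_reps = config@bioReps,
    seed_cells = config@seedCells, gain = config@gain,
    background = config@background, noise_cv = config@noiseCV,
    seed = config@seed), path)
  invisible(path)
}

#' Simulate raw plate tables with known ground truth
#'
#' Emits one endpoint plate and one time-zero plate per cell line and
#' biological replicate. Untreated cells double every `doubling_time_h`
#' hours; drug at concentration c rescales the growth rate by
#' log2(GR_true(c) + 1), where GR_true is the sigmoid at the configured
#' true parameters. Luminescence is cell count times gain under
#' multiplicative log-normal noise, plus the additive background; blank
#' wells read the background alone (with the same multiplicative noise).
#' Output is deterministic under the configured seed, with per-plate
#' streams derived from it.
#'
#' @param config a [GRSimConfig].
#' @return A list with `wells` (a raw [PlateData], blanks included) and
#'   `truth` (list of `params` -- the true curve parameters with true
#'   control divisions per line -- and `gr` -- the true GR value per cell
#'   line / perturbagen / dose).
#' @export
simulatePlates <- function(config) {
  stopifnot(methods::is(config, "GRSimConfig"))
  methods::validObject(config)
  tr <- config@truth
  gr_true <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    g <- grSigmoid(config@doses, tr$gr_inf[i], tr$gec50[i], tr$h_gr[i])
    data.frame(cell_line = tr$cell_line[i], perturbagen = tr$perturbagen[i],
               concentration = config@doses, gr_true = g)
  }))
  if (any(gr_true$gr_true <= -1))
    stop("simulatePlates: true GR <= -1 at a tested dose; the exponential ",
         "growth model cannot represent super-complete kill")

  sigma <- sqrt(log(1 + config@noiseCV^2))
  noisy <- function(expected, n) {
    if (config@noiseCV == 0) return(rep(expected, length.out = n))
    # mean-preserving log-normal: E[value] = expected
    expected * exp(stats::rnorm(n, -sigma^2 / 2, sigma))
  }
  t <- config@assayDurationH

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }

  rows <- list()
  plate_index <- 0L
  for (li in seq_len(nrow(config@cellLines))) {
    line <- config@cellLines$cell_line[li]
    td <- config@cellLines$doubling_time_h[li]
    k0 <- 1 / td  # divisions per hour
    line_truth <- gr_true[gr_true$cell_line == line, , drop = FALSE]
    for (rep_i in seq_len(config@bioReps)) {
      plate_index <- plate_index + 1L
      set.seed(config@seed + plate_index)
      rep_id <- as.character(rep_i)
      p_end <- sprintf("%s_r%d_end", line, rep_i)
      p_t0 <- sprintf("%s_r%d_t0", line, rep_i)

      ctrl_cells <- config@seedCells * 2^(k0 * t)
      mk <- function(role, plate, perturbagen, conc, expected, n) {
        data.frame(cell_line = line, perturbagen = perturbagen,
                   concentration = conc, role = role, replicate = rep_id,
                   plate = plate, value = noisy(expected, n))
      }
      # endpoint plate: treated wells, vehicle controls, blanks
      for (pi in seq_len(nrow(line_truth))) {
        ratio <- log2(line_truth$gr_true[pi] + 1)
        cells <- config@seedCells * 2^(k0 * t * ratio)
        rows[[length(rows) + 1L]] <- mk("treated", p_end,
          line_truth$perturbagen[pi], line_truth$concentration[pi],
          cells * config@gain + config@background, config@techReps)
      }
      rows[[length(rows) + 1L]] <- mk("control", p_end, "", 0,
        ctrl_cells * config@gain + config@background, config@nCtrlWells)
      rows[[length(rows) + 1L]] <- mk("blank", p_end, "", NA_real_,
        config@background, config@nBlankWells)
      # time-zero plate: untreated wells at seeding density, blanks
      rows[[length(rows) + 1L]] <- mk("time0", p_t0, "", NA_real_,
        config@seedCells * config@gain + config@background,
        config@nTime0Wells)
      rows[[length(rows) + 1L]] <- mk("blank", p_t0, "", NA_real_,
        config@background, config@nBlankWells)
    }
  }
  wells <- do.call(rbind, rows)
  # background noise on blanks means a "cell" well expectation includes the
  # additive background exactly; values are always non-negative because the
  # log-normal factor is positive
  wells <- .coerceWells(wells)
  rownames(wells) <- NULL
  params <- merge(tr, data.frame(
    cell_line = config@cellLines$cell_line,
    doubling_time_h = config@cellLines$doubling_time_h,
    true_divisions = config@assayDurationH / config@cellLines$doubling_time_h))
  list(wells = methods::new("PlateData", wells = wells, corrected = FALSE),
       truth = list(params = params, gr = gr_true))
}

#' Traditional IC50 / Emax from relative cell counts
#'
#' The conventional viability metrics, provided for contrast with the GR
#' metrics: a bounded sigmoid fit of the relative cell count
#' x(c)/x_ctrl (asymptote in \[0, 1\], Hill coefficient in \[0.1, 5\],
#' midpoint within two orders of magnitude of the tested range), from
#' which IC50 is the concentration where the fitted relative count crosses
#' 0.5 (`Inf` when it never does) and Emax is the measured relative count
#' at the highest tested dose. Unlike GR50/GRmax these depend on the
#' division rate of the untreated culture, which is the confounding the GR
#' framework removes.
#'
#' @param concentration tested concentrations, micromolar, >= 4 distinct.
#' @param relativeCount relative cell counts x(c)/x_ctrl, same length.
#' @param options a [grFitOptions()] list.
#' @return list with `ic50`, `e_max`, and the fitted parameters
#'   (`e_inf`, `ec50`, `h`, `fit_class`).
#' @export
traditionalMetrics <- function(concentration, relativeCount,
                               options = grFitOptions()) {
  stopifnot(length(concentration) == length(relativeCount))
  if (any(concentration <= 0))
    stop("traditionalMetrics: concentrations must be positive")
  if (length(unique(concentration)) < 4L)
    stop("traditionalMetrics: need at least 4 distinct concentrations")
  c_min <- min(concentration)
  c_max <- max(concentration)
  lower <- c(0, log10(c_min) - 2, 0.1)
  upper <- c(1, log10(c_max) + 2, 5)
  sse <- function(par) {
    pred <- par[1L] + (1 - par[1L]) / (1 + (concentration / 10^par[2L])^par[3L])
    sum((relativeCount - pred)^2)
  }
  starts <- list(
    c(max(min(relativeCount), 0), mean(log10(c(c_min, c_max))), 2),
    c(max(min(relativeCount), 0),
      log10(concentration[which.min(abs(relativeCount -
        (1 + max(min(relativeCount), 0)) / 2))]), 1))
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(stats::optim(p0, sse, method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(factr = options$factr,
                                                maxit = options$maxit)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  e_max <- mean(relativeCount[concentration == max(concentration)])
  if (is.null(best))
    return(list(ic50 = NA_real_, e_max = e_max, e_inf = NA_real_,
                ec50 = NA_real_, h = NA_real_, fit_class = "failed"))
  e_inf <- best$par[1L]
  ec50 <- 10^best$par[2L]
  h <- best$par[3L]
  rss_flat <- sum((relativeCount - mean(relativeCount))^2)
  flat <- rss_flat <= best$value ||
    (isTRUE(options$flatTest) && {
      n <- length(relativeCount)
      df2 <- n - 3L
      f_stat <- ((rss_flat - best$value) / 2) / (best$value / max(df2, 1L))
      p <- stats::pf(f_stat, 2, max(df2, 1L), lower.tail = FALSE)
      !is.finite(p) || p >= options$fTestAlpha
    })
  if (flat) {
    m <- mean(relativeCount)
    return(list(ic50 = if (m > 0.5) Inf else -Inf, e_max = e_max,
                e_inf = m, ec50 = NA_real_, h = NA_real_,
                fit_class = "flat"))
  }
  ic50 <- if (e_inf >= 0.5) Inf
          else ec50 * (0.5 / (0.5 - e_inf))^(1 / h)
  list(ic50 = ic50, e_max = e_max, e_inf = e_inf, ec50 = ec50, h = h,
       fit_class = "sigmoid")
}
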