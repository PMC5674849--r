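# shared fixture builders: everything is generated in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal well data.frame in the internal column layout
makeWellDF <- function(cell_line = "L1", perturbagen = "", concentration = NA_real_,
                       role, replicate = "1", plate = "P1", value) {
  data.frame(cell_line = cell_line, perturbagen = perturbagen,
             concentration = concentration, role = role,
             replicate = replicate, plate = plate, value = value,
             stringsAsFactors = FALSE)
}

# one complete plate: treated triplicates at given doses, controls, time0,
# blanks; values chosen so that corrected counts are exact
makeSmallPlate <- function(doses = c(1, 5, 25), treated = c(400, 300, 200),
                           ctrl = 800, t0 = 200, bg = 100, nCtrl = 2,
                           nT0 = 2, nBlank = 2, plate = "P1",
                           t0plate = "T0") {
  stopifnot(length(doses) == length(treated))
  rbind(
    do.call(rbind, lapply(seq_along(doses), function(i)
      makeWellDF(perturbagen = "drugA", concentration = doses[i],
                 role = "treated", plate = plate,
                 value = rep(treated[i] + bg, 3)))),
    makeWellDF(concentration = 0, role = "control", plate = plate,
               value = rep(ctrl + bg, nCtrl)),
    makeWellDF(role = "blank", plate = plate, value = rep(bg, nBlank)),
    makeWellDF(role = "time0", plate = t0plate, value = rep(t0 + bg, nT0)),
    makeWellDF(role = "blank", plate = t0plate, value = rep(bg, nBlank)))
}

asPlateData <- function(df) methods::new("PlateData", wells = df)

# GRTable built directly from control division counts (x_0 = 1000), with a
# consistent gr_value for a mid-strength response
makeGRTable <- function(divisions, gr = NULL, cell_line = "L1",
                        perturbagen = "drugA", concentration = 1,
                        replicate = "1", assay = 72) {
  x0 <- 1000
  xctrl <- x0 * 2^divisions
  if (is.null(gr)) gr <- rep(0.5, length(divisions))
  xc <- ifelse(divisions != 0, x0 * 2^(log2(gr + 1) * divisions), x0)
  d <- data.frame(cell_line = rep_len(cell_line, length(divisions)),
                  perturbagen = rep_len(perturbagen, length(divisions)),
                  concentration = rep_len(concentration, length(divisions)),
                  replicate = rep_len(replicate, length(divisions)),
                  plate = paste0("P", seq_along(divisions)),
                  x_c = xc, x_ctrl = xctrl, x_0 = x0,
                  relative_count = xc / xctrl,
                  gr_value = ifelse(divisions != 0, gr, NA_real_),
                  control_divisions = divisions,
                  division_time_h = ifelse(divisions > 0, assay / divisions, Inf),
                  flag = ifelse(divisions > 0, "ok",
                                ifelse(divisions == 0, "undefined_growth",
                                       "shrinking_control")))
  methods::new("GRTable", data = d, assayDurationH = assay)
}

# nine-point 1:5 dilution from 33 uM, as in the assay design
nineDoses <- function(top = 33) top / 5^(8:0)

# quick one-line, one-drug simulation config
quickSimConfig <- function(doubling = 36, gr_inf = 0.2, gec50 = 0.5,
                           h_gr = 2, noiseCV = 0, seed = 1, bioReps = 2,
                           perturbagen = "drugA", top = 33, ...) {
  simulationConfig(
    cellLines = data.frame(cell_line = "L1", doubling_time_h = doubling),
    truth = data.frame(perturbagen = perturbagen, gr_inf = gr_inf,
                       gec50 = gec50, h_gr = h_gr),
    topConcentration = top, noiseCV = noiseCV, seed = seed,
    bioReps = bioReps, ...)
}
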