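makeFit <- function(grInf, gec50, hGR, cMin = 33 / 5^8, cMax = 33,
                    fitClass = "sigmoid") {
  methods::new("GRFit", grInf = grInf,
               gec50 = if (fitClass == "sigmoid") gec50 else NA_real_,
               hGR = if (fitClass == "sigmoid") hGR else NA_real_,
               fitClass = fitClass, rSquared = 0.99, pFlat = 0.01,
               cMin = cMin, cMax = cMax, nPoints = 9L, converged = TRUE)
}

test_that("GR50 inversion matches the hand-derived closed form and censoring rules", {
  # hand inversion: gec50 * (0.5 / (0.5 - 0.4))^(1/1) = 5 uM
  expect_equal(gr50FromFit(makeFit(0.4, 1, 1)), 5)
  # GRinf above 0.5: the curve never reaches 0.5
  expect_identical(gr50FromFit(makeFit(0.6, 1, 1)), Inf)
  # solved value more than 3.16-fold above the top dose is censored
  expect_identical(gr50FromFit(makeFit(0.4, 1, 1, cMax = 1)), Inf)
  # just inside the extrapolation window is kept: 5 < 2 * 10^0.5 = 6.32
  expect_equal(gr50FromFit(makeFit(0.4, 1, 1, cMax = 2)), 5)
  # flat fits: +Inf above 0.5, below-range sentinel otherwise
  expect_identical(gr50FromFit(makeFit(0.8, NA, NA, fitClass = "flat")), Inf)
  expect_identical(gr50FromFit(makeFit(-0.2, NA, NA, fitClass = "flat")), -Inf)
})

test_that("closed-form GR50 agrees with numeric root-finding across random fits", {
  set.seed(17)
  n_checked <- 0
  for (i in 1:1000) {
    gi <- runif(1, -1, 0.45)
    g50 <- 10^runif(1, -3, 2)
    h <- runif(1, 0.1, 5)
    fit <- makeFit(gi, g50, h, cMin = 1e-4, cMax = 1e6)
    gr50 <- gr50FromFit(fit)
    if (!is.finite(gr50)) next
    root <- uniroot(function(c) grSigmoid(c, gi, g50, h) - 0.5,
                    lower = 1e-12, upper = 1e12, tol = 1e-12)$root
    expect_equal(gr50, root, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 900)
})

test_that("the two GR50 infinity rules fire exactly when printed conditions hold", {
  set.seed(23)
  for (i in 1:300) {
    gi <- runif(1, -1, 1)
    g50 <- 10^runif(1, -2, 1)
    h <- runif(1, 0.1, 5)
    cmax <- 10^runif(1, -1, 2)
    fit <- makeFit(gi, g50, h, cMin = cmax / 5^8, cMax = cmax)
    gr50 <- gr50FromFit(fit)
    if (gi >= 0.5) {
      expect_identical(gr50, Inf)
    } else {
      closed <- g50 * (0.5 / (0.5 - gi))^(1 / h)
      if (closed > cmax * 10^0.5) expect_identical(gr50, Inf)
      else expect_equal(gr50, closed)
    }
  }
})

test_that("GRmax takes the top-dose value and clamps to [-1, 1] with a flag", {
  expect_equal(as.numeric(grMax(c(1, 5, 25), c(0.8, 0.3, -0.2))), -0.2)
  expect_equal(as.numeric(grMax(c(1, 5, 25), c(1, 1, 1))), 1)
  g <- grMax(c(1, 5, 25), c(0.8, 0.3, -1.3))
  expect_equal(as.numeric(g), -1)
  expect_true(attr(g, "out_of_range"))
  expect_false(attr(grMax(c(1, 5), c(0.5, 0.2)), "out_of_range"))
  # replicate values at the top dose are averaged
  expect_equal(as.numeric(grMax(c(5, 25, 25), c(0.5, 0.1, 0.3))), 0.2)
})

test_that("GRAOC integrates (1 - GR) per log10 unit with the stated anchors", {
  expect_equal(grAOC(c(1, 10, 100), rep(1, 3)), 0)   # no effect anywhere
  expect_equal(grAOC(c(1, 10, 100), rep(0, 3)), 1)   # full cytostasis
  expect_equal(grAOC(c(1, 10), c(1, 0.5)), 0.25)     # hand trapezoid
  expect_error(grAOC(5, 0.5), "2 distinct")

  # fine-grid oracle: integrate the linear-in-log10 interpolant numerically
  set.seed(31)
  for (i in 1:50) {
    conc <- sort(10^runif(sample(3:9, 1), -3, 2))
    gr <- runif(length(conc), -1, 1)
    lg <- log10(conc)
    grid <- sort(unique(c(seq(min(lg), max(lg), length.out = 5000), lg)))
    y <- 1 - approx(lg, gr, xout = grid)$y
    # dense trapezoid over the linear interpolant, nodes included (exact)
    oracle <- sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2) /
      (max(lg) - min(lg))
    expect_equal(grAOC(conc, gr), oracle, tolerance = 1e-10)
  }
})

test_that("GRAOC is log-translation invariant and monotone in the curve", {
  set.seed(37)
  for (i in 1:50) {
    conc <- nineDoses(10^runif(1, 0, 2.3))
    gr <- runif(9, -1, 1)
    a <- 10^runif(1, -2, 2)
    expect_equal(grAOC(a * conc, gr), grAOC(conc, gr), tolerance = 1e-10)
    # pointwise-lower GR never lowers the area over the curve
    drop <- runif(9, 0, 0.5)
    expect_gte(grAOC(conc, gr - drop), grAOC(conc, gr))
  }
})

test_that("metric records assemble all six metrics with flags", {
  conc <- nineDoses(65.61)
  gr <- grSigmoid(conc, 0.2, 0.5, 2)
  fit <- fitGRCurve(conc, gr)
  rec <- extractGRMetrics(conc, gr, fit, "L1", "drugA")
  expect_equal(rec$gr50, 0.5 * (0.5 / 0.3)^(1 / 2), tolerance = 1e-4)
  expect_equal(rec$gr_inf, 0.2, tolerance = 1e-4)
  expect_equal(rec$gec50, 0.5, tolerance = 1e-3)
  expect_equal(rec$h_gr, 2, tolerance = 1e-3)
  expect_equal(rec$gr_max, grSigmoid(65.61, 0.2, 0.5, 2), tolerance = 1e-6)
  expect_equal(rec$c_max, 65.61)
  expect_equal(rec$fit_class, "sigmoid")

  # flat at GR = 1: no effect at all
  rec1 <- extractGRMetrics(conc, rep(1, 9), fitGRCurve(conc, rep(1, 9)),
                           "L1", "drugB")
  expect_identical(rec1$gr50, Inf)
  expect_equal(rec1$gr_aoc, 0)
  expect_equal(rec1$gr_max, 1)

  # flat cytotoxic: below-range sentinel, noted
  recs <- extractGRMetrics(conc, rep(-0.5, 9), fitGRCurve(conc, rep(-0.5, 9)),
                           "L1", "drugC")
  expect_identical(recs$gr50, -Inf)
  expect_equal(recs$gr50_note, "below_range")
  expect_equal(recs$gr_max, -0.5)
})

test_that("computeGRMetrics averages replicates, fits per pair and flags ranges", {
  conc <- nineDoses()
  d <- rbind(
    data.frame(cell_line = "L1", perturbagen = "drugA", concentration = conc,
               replicate = "1", gr_value = grSigmoid(conc, 0.2, 0.5, 2) + 0.05),
    data.frame(cell_line = "L1", perturbagen = "drugA", concentration = conc,
               replicate = "2", gr_value = grSigmoid(conc, 0.2, 0.5, 2) - 0.05),
    data.frame(cell_line = "L2", perturbagen = "drugA", concentration = conc,
               replicate = "1", gr_value = grSigmoid(conc, 0.1, 1, 1)),
    data.frame(cell_line = "L3", perturbagen = "drugA",
               concentration = conc / 10, replicate = "1",
               gr_value = grSigmoid(conc / 10, -0.3, 0.1, 1)))
  m <- metrics(computeGRMetrics(d))
  expect_equal(nrow(m), 3L)
  l1 <- m[m$cell_line == "L1", ]
  # replicate noise cancels exactly at each dose, so recovery is exact
  expect_equal(l1$gr_inf, 0.2, tolerance = 1e-4)
  expect_equal(l1$gec50, 0.5, tolerance = 1e-3)
  # the one record tested on a shifted range is flagged, the others not
  expect_equal(m$range_differs[order(m$cell_line)], c(FALSE, FALSE, TRUE))
})
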