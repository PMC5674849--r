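test_that("the division filters use strict thresholds in the stated order", {
  # 0.25 divisions -> low growth; exactly 0.3 -> retained (strict "fewer than")
  tab <- makeGRTable(c(0.25, 0.3, 2))
  res <- filterLowGrowth(tab)
  expect_equal(unname(qcCounts(res$report)),
               c(3L, 1L, 1L, 1L))
  d <- grValues(res$retained)
  expect_equal(d$control_divisions, 2)
  # 0.3 divisions over 72 h = 240 h division time -> slow-division rule,
  # but only because low-growth (rule 1) did not already fire
  expect_equal(res$report@nExcludedSlowDivision, 1L)

  # division time 90 h (0.8 divisions over 72 h) -> excluded as slow
  tab2 <- makeGRTable(c(72 / 90, 72 / 80, 1.5))
  res2 <- filterLowGrowth(tab2)
  expect_equal(res2$report@nExcludedLowGrowth, 0L)
  expect_equal(res2$report@nExcludedSlowDivision, 1L)  # 80 h exactly retained
  expect_equal(res2$report@nRetained, 2L)
})

test_that("filter bookkeeping matches a constructed fixture exactly", {
  # 10 records: 2 below 0.3 divisions, 1 at 85 h division time, 7 clean
  div_85h <- 72 / 85
  tab <- makeGRTable(c(0.1, 0.25, div_85h, rep(c(1, 1.5, 2, 2.5, 3, 1.2, 0.95), 1)))
  res <- filterLowGrowth(tab)
  counts <- qcCounts(res$report)
  expect_equal(unname(counts["n_input"]), 10L)
  expect_equal(unname(counts["n_excluded_low_growth"]), 2L)
  expect_equal(unname(counts["n_excluded_slow_division"]), 1L)
  expect_equal(unname(counts["n_retained"]), 7L)
  # attribution sums to the input count (class invariant, but check the data)
  expect_equal(sum(counts[-1]), unname(counts["n_input"]))
})

test_that("flagged degenerate records fall under the low-growth rule", {
  tab <- makeGRTable(c(-0.5, 0, 1))
  res <- filterLowGrowth(tab)
  expect_equal(res$report@nExcludedLowGrowth, 2L)
  expect_equal(res$report@nRetained, 1L)
})

test_that("filters are idempotent and monotone in the cutoff", {
  set.seed(41)
  tab <- makeGRTable(runif(50, -0.2, 3))
  once <- filterLowGrowth(tab)
  twice <- filterLowGrowth(once$retained)
  expect_equal(grValues(twice$retained), grValues(once$retained))
  expect_equal(twice$report@nExcludedLowGrowth, 0L)
  expect_equal(twice$report@nExcludedSlowDivision, 0L)

  retained_at <- vapply(c(0.1, 0.3, 0.6, 0.9, 1.5), function(cut) {
    filterLowGrowth(tab, minDivisions = cut)$report@nRetained
  }, integer(1))
  expect_true(all(diff(retained_at) <= 0))
})

test_that("per-cell-line exclusion counts are reported", {
  tab <- makeGRTable(c(0.1, 1, 1, 0.2, 0.5),
                     cell_line = c("A", "A", "B", "B", "B"))
  rep_ <- filterLowGrowth(tab)$report
  pcl <- rep_@perCellLine
  expect_equal(pcl$n_low_growth[pcl$cell_line == "A"], 1L)
  expect_equal(pcl$n_low_growth[pcl$cell_line == "B"], 1L)
  expect_equal(pcl$n_retained[pcl$cell_line == "A"], 1L)
})

test_that("replicate averaging computes mean GR and the SEM by hand-checked formula", {
  tab <- makeGRTable(c(1, 1), gr = c(0.4, 0.6), replicate = c("1", "2"))
  avg <- averageReplicates(tab)
  expect_equal(nrow(avg), 1L)
  expect_equal(avg$gr_value, 0.5)
  expect_equal(avg$gr_sem, 0.1)        # sd(0.4, 0.6)/sqrt(2) = 0.1
  expect_equal(avg$n_replicates, 2L)

  one <- averageReplicates(makeGRTable(1, gr = 0.7))
  expect_equal(one$gr_value, 0.7)
  expect_true(is.na(one$gr_sem))
  expect_false(one$sem_defined)

  same <- averageReplicates(makeGRTable(c(1, 1, 1), gr = rep(0.3, 3),
                                        replicate = c("1", "2", "3")))
  expect_equal(same$gr_sem, 0)
})

test_that("replicate SEM matches the closed-form sigma/sqrt(n) of the noise", {
  # GR replicates drawn iid N(mu, sigma): E[SEM] ~ sigma/sqrt(n)
  set.seed(47)
  sigma <- 0.12
  n <- 4
  sems <- replicate(300, {
    gr <- rnorm(n, 0.4, sigma)
    tab <- makeGRTable(rep(1.5, n), gr = gr,
                       replicate = as.character(seq_len(n)))
    averageReplicates(tab)$gr_sem
  })
  # E[sd] = sigma * c4 correction; Monte-Carlo tolerance
  expect_equal(mean(sems), sigma / sqrt(n), tolerance = 0.05)
})

test_that("the SEM-vs-cutoff sweep reproduces the quality-vs-growth trend", {
  # construct replicates whose noise scales inversely with division count:
  # fast growers have tight replicates, slow growers noisy ones
  set.seed(53)
  divs <- runif(60, 0.1, 3)
  rows <- lapply(seq_along(divs), function(i) {
    noise <- 0.02 / divs[i]
    grValues(makeGRTable(rep(divs[i], 3),
                         gr = 0.5 + rnorm(3, 0, noise),
                         replicate = c("1", "2", "3"),
                         perturbagen = paste0("d", i)))
  })
  tab <- methods::new("GRTable", data = do.call(rbind, rows),
                      assayDurationH = 72)
  sweep <- semVsCutoffSweep(tab, cutoffs = c(0, 0.3, 0.9, 1.5))
  expect_equal(nrow(sweep), 4L)
  # unfiltered row equals the cutoff-0 row by construction
  expect_equal(sweep$n_retained[1], nrow(grValues(tab)))
  # percentiles shrink (weakly) as the cutoff rises
  expect_true(all(diff(sweep$gr_sem_p95) <= 1e-12))
  expect_true(all(diff(sweep$gr_sem_p50) <= 1e-12))
  # extreme cutoff empties the table and is flagged
  ext <- semVsCutoffSweep(tab, cutoffs = 10)
  expect_true(ext$empty)
  expect_true(is.na(ext$gr_sem_p50))
})

test_that("per-replicate fit statistics report finite log10 SEM percentiles", {
  conc <- nineDoses()
  set.seed(59)
  rows <- lapply(c("1", "2"), function(r) {
    gr <- grSigmoid(conc, 0.1, 0.5, 2) + rnorm(9, 0, 0.03)
    d <- grValues(makeGRTable(rep(2, 9), gr = gr, replicate = r,
                              concentration = conc))
    d
  })
  tab <- methods::new("GRTable", data = do.call(rbind, rows),
                      assayDurationH = 72)
  sweep <- semVsCutoffSweep(tab, cutoffs = 0, fitStatistics = TRUE)
  expect_true(is.finite(sweep$r2_p50))
  expect_true(is.finite(sweep$log10_gec50_sem_p50))
  expect_gte(sweep$log10_gec50_sem_p50, 0)
})
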