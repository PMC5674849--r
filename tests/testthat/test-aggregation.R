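makeMetricsRecords <- function(gr50, cell_line = paste0("L", seq_along(gr50)),
                               perturbagen = "drugA", gr_max = 0,
                               gec50 = abs(gr50)) {
  methods::new("GRMetrics", data = data.frame(
    cell_line = cell_line, perturbagen = perturbagen, gr50 = gr50,
    gr_max = rep_len(gr_max, length(gr50)), gr_aoc = 0.3, gr_inf = 0.1,
    h_gr = 2, gec50 = gec50, c_min = 0.001, c_max = 33, n_points = 9L,
    fit_class = "sigmoid", r_squared = 0.95, gr_max_clamped = FALSE,
    gr50_note = "", range_differs = FALSE))
}

test_that("aggregation reports median and quartiles per metric and group", {
  m <- makeMetricsRecords(c(1, 10, 100), gr_max = c(-0.2, 0, 0.4))
  agg <- aggregateMetrics(m, by = "perturbagen")
  gmax <- agg[agg$metric == "gr_max", ]
  expect_equal(gmax$median, 0)
  expect_equal(gmax$q25, -0.1)      # type-7 interpolation on three values
  expect_equal(gmax$q75, 0.2)
  expect_equal(gmax$n_cell_lines, 3L)
  # concentration metrics aggregate in log10 space: median is geometric
  g50 <- agg[agg$metric == "gr50", ]
  expect_equal(g50$median, 10)
  expect_equal(g50$q25, 10^mean(c(0, 1)))   # sqrt(10)
  # quartile ordering holds for every metric
  expect_true(all(agg$q25 <= agg$median & agg$median <= agg$q75, na.rm = TRUE))
})

test_that("identical records aggregate to themselves at every quantile", {
  m <- makeMetricsRecords(rep(5, 4))
  agg <- aggregateMetrics(m)
  for (met in unique(agg$metric)) {
    row <- agg[agg$metric == met, ]
    expect_equal(row$q25, row$median)
    expect_equal(row$q75, row$median)
  }
  expect_equal(agg$median[agg$metric == "gr50"], 5)
})

test_that("infinite GR50 values survive aggregation by rank semantics", {
  m <- makeMetricsRecords(c(Inf, Inf, Inf))
  agg <- aggregateMetrics(m)
  expect_identical(agg$median[agg$metric == "gr50"], Inf)
  # a majority of resistant lines pushes the median to infinity,
  # rather than being dropped and biasing toward sensitivity
  m2 <- makeMetricsRecords(c(1, Inf, Inf))
  expect_identical(aggregateMetrics(m2)$median[
    aggregateMetrics(m2)$metric == "gr50"], Inf)
})

test_that("class-level aggregation uses annotations and defaults to N/A", {
  m <- methods::new("GRMetrics", data = rbind(
    metrics(makeMetricsRecords(c(1, 10), perturbagen = "drugA")),
    metrics(makeMetricsRecords(c(5, 50), perturbagen = "drugB")),
    metrics(makeMetricsRecords(2, perturbagen = "drugC"))))
  ann <- data.frame(perturbagen = c("drugA", "drugB"),
                    drug_class = c("TUBB", "TUBB"))
  agg <- aggregateMetrics(m, ann, by = "drug_class")
  expect_setequal(unique(agg$group), c("TUBB", "N/A"))
  tubb_g50 <- agg$median[agg$group == "TUBB" & agg$metric == "gr50"]
  expect_equal(tubb_g50, 10^median(log10(c(1, 10, 5, 50))))
  # membership partition: unique cell lines counted per class, none lost
  expect_equal(agg$n_cell_lines[agg$group == "TUBB" & agg$metric == "gr50"], 2L)
  expect_equal(agg$n_cell_lines[agg$group == "N/A" & agg$metric == "gr50"], 1L)
})

test_that("the annotation reader validates its schema and uniqueness", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(perturbagen = c("a", "b"),
                       drug_class = c("HDAC", "MAPK")), path,
            row.names = FALSE)
  ann <- readClassAnnotations(path)
  expect_equal(ann$drug_class, c("HDAC", "MAPK"))
  write.csv(data.frame(perturbagen = c("a", "a"),
                       drug_class = c("HDAC", "MAPK")), path,
            row.names = FALSE)
  expect_error(readClassAnnotations(path), "more than one class")
  write.csv(data.frame(drug = "a", drug_class = "HDAC"), path,
            row.names = FALSE)
  expect_error(readClassAnnotations(path), "perturbagen")
})

test_that("response classes follow the potency/efficacy quadrants", {
  expect_equal(classifyResponse(0.1, -0.3), "potent-cytotoxic")
  expect_equal(classifyResponse(Inf, 0.6), "weak-cytostatic")
  expect_equal(classifyResponse(0.5, 0.2), "potent-cytostatic")
  expect_equal(classifyResponse(30, -0.1), "weak-cytotoxic")
  # boundary: GR50 exactly at the threshold counts as potent
  expect_equal(classifyResponse(1, 0.2), "potent-cytostatic")
  # GRmax exactly 0 (fully cytostatic) is not cytotoxic
  expect_equal(classifyResponse(0.5, 0), "potent-cytostatic")
  expect_equal(classifyResponse(c(0.1, Inf), c(-1, 1)),
               c("potent-cytotoxic", "weak-cytostatic"))
})
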