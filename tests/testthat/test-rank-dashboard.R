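## every printed threshold of the graded metrics, top band first
gradedBands <- list(
  A = c(80, 70, 60, 50),
  F = c(0.05, 0.02, 0.01, 0.0075),
  L = c(10000, 5000, 2000, 1000),
  NRF = c(0.8, 0.7, 0.6, 0.5),
  N = c(10000, 5000, 2000, 1000),
  C = c(0.9, 0.75, 0.66, 0.5),
  P = c(10000, 5000, 2000, 1000),
  R = c(30e6, 25e6, 20e6, 15e6),
  S = c(0.2, 0.1, 0.05, 0.02)
)
labels <- c("Excellent", "Good", "Average", "Below-average", "Poor")

test_that("every printed boundary maps to the higher band (inclusive >=)", {
  for (m in names(gradedBands)) {
    th <- gradedBands[[m]]
    for (i in seq_along(th)) {
      expect_equal(rankMetric(m, th[i]), labels[i],
                   label = sprintf("%s at %g", m, th[i]))
      ## just below the boundary falls to the next band down
      expect_equal(rankMetric(m, th[i] * (1 - 1e-9)), labels[i + 1L],
                   label = sprintf("%s below %g", m, th[i]))
    }
  }
  ## two-band and three-band special metrics
  expect_equal(rankMetric("NSC", 1.045), "Excellent")
  expect_equal(rankMetric("NSC", 1.044), "Poor")
  expect_equal(rankMetric("RSC", 1), "Excellent")
  expect_equal(rankMetric("RSC", 0.99), "Good")
  expect_equal(rankMetric("RSC", 0.75), "Good")
  expect_equal(rankMetric("RSC", 0.74), "Poor")
  expect_equal(rankMetric("E", 9.99), "Excellent")
  expect_equal(rankMetric("E", -9.99), "Excellent")
  expect_equal(rankMetric("E", 24), "Poor")
  ## overall quality thresholds
  expect_equal(rankMetric("Q", 2), "Excellent")
  expect_equal(rankMetric("Q", 1), "Good")
  expect_equal(rankMetric("Q", 0), "Average")
  expect_equal(rankMetric("Q", -1), "Below-average")
  expect_equal(rankMetric("Q", -1.01), "Poor")
})

test_that("spec spot checks: mid-band values", {
  expect_equal(rankMetric("NRF", 0.55), "Below-average")
  expect_equal(rankMetric("F", 0.009), "Below-average")
  expect_true(is.na(rankMetric("FragWidth", 200)))
  expect_true(is.na(rankMetric("ReadLength", 75)))
  expect_error(rankMetric("bogus", 1), "unknown metric")
})

test_that("pass/warn/fail metrics map onto the five-level scale", {
  for (m in c("B", "D")) {
    expect_equal(rankMetric(m, "pass"), "Excellent")
    expect_equal(rankMetric(m, "warn"), "Average")
    expect_equal(rankMetric(m, "fail"), "Poor")
    expect_true(is.na(rankMetric(m, NA)))
    expect_error(rankMetric(m, "maybe"), "pass/warn/fail")
  }
})

test_that("increasing a metric value never lowers its rank", {
  set.seed(141)
  for (m in names(gradedBands)) {
    hi <- gradedBands[[m]][1]
    vals <- sort(runif(50, 0, hi * 1.5))
    scores <- rankScore(vapply(vals, function(v) rankMetric(m, v), ""))
    expect_true(all(diff(scores) >= 0), label = m)
  }
  ## E oriented as -|E|
  eVals <- c(0, 5, 9.99, 10, 30)
  eScores <- rankScore(vapply(eVals, function(v) rankMetric("E", v),
                              ""))
  expect_true(all(diff(eScores) <= 0))
})

test_that("rank labels, scores and colors are a consistent scale", {
  expect_equal(unname(rankScore(labels)), c(2, 1, 0, -1, -2))
  expect_true(is.na(rankScore(NA_character_)))
  cols <- rankColor(labels)
  expect_true(all(grepl("^#[0-9a-f]{6}$", cols)))
  expect_equal(length(unique(cols)), 5L)
})

allExcellent <- list(A = 90, B = "pass", E = 0, F = 0.06, L = 20000,
                     NRF = 0.9, N = 20000, NSC = 1.2, D = "pass",
                     C = 0.95, P = 20000, R = 40e6, RSC = 1.2,
                     S = 0.25)
allPoor <- list(A = 10, B = "fail", E = 50, F = 0.001, L = 10,
                NRF = 0.1, N = 10, NSC = 1.0, D = "fail", C = 0.1,
                P = 10, R = 1e6, RSC = 0.1, S = 0.001)

test_that("overall quality is the mean score with its own thresholds", {
  pE <- buildMetricPanel(allExcellent)
  expect_equal(overallQuality(pE)$Q, 2)
  expect_equal(overallQuality(pE)$rank, "Excellent")
  pP <- buildMetricPanel(allPoor)
  expect_equal(overallQuality(pP)$Q, -2)
  expect_equal(overallQuality(pP)$rank, "Poor")
  ## scores [2, 0, -2] average to 0 -> Average
  pMix <- buildMetricPanel(list(NRF = 0.9, C = 0.7, F = 0.001))
  expect_equal(overallQuality(pMix)$Q, 0)
  expect_equal(overallQuality(pMix)$rank, "Average")
  pOne <- buildMetricPanel(list(NSC = 1.0))
  expect_equal(overallQuality(pOne)$Q, -2)
  expect_equal(overallQuality(pOne)$rank, "Poor")
  expect_error(buildMetricPanel(list(FragWidth = 200)), "rankable")
})

test_that("a panel of uniformly-labelled metrics scores that label", {
  allAverage <- list(A = 65, B = "warn", F = 0.015, L = 3000,
                     NRF = 0.65, N = 3000, D = "warn", C = 0.7,
                     P = 3000, R = 22e6, S = 0.07)
  p <- buildMetricPanel(allAverage)
  expect_equal(overallQuality(p)$Q, 0)
  expect_equal(overallQuality(p)$rank, "Average")
})

test_that("missing metrics are excluded from Q, not penalised", {
  p1 <- buildMetricPanel(allExcellent)
  p2 <- buildMetricPanel(allExcellent[setdiff(names(allExcellent),
                                              c("B", "D", "N"))])
  expect_equal(overallQuality(p2)$Q, overallQuality(p1)$Q)
  e <- panelEntries(p2)
  expect_true(is.na(e$rank[e$metric == "N"]))
})

test_that("the report renders deterministic TSV and color-flagged HTML", {
  p <- buildMetricPanel(list(NRF = 0.85, F = 0.03, C = 0.7))
  d1 <- withr::local_tempdir()
  paths <- renderReport(p, d1, prefix = "t")
  tsv <- readLines(paths[["tsv"]])
  ## header + one row per registry metric + overall
  expect_equal(tsv[1], "metric\tvalue\trank\tscore")
  expect_equal(length(tsv), 1 + nrow(panelEntries(p)) + 1)
  last <- strsplit(tsv[length(tsv)], "\t")[[1]]
  expect_equal(last[1], "Overall quality")
  ## missing metrics show NA value and "-" rank
  aRow <- strsplit(tsv[2], "\t")[[1]]
  expect_equal(aRow[2:4], c("NA", "-", "-"))
  ## fixed formatting: ratios at 4 decimals
  nrfRow <- grep("Non-redundant", tsv, value = TRUE)
  expect_match(nrfRow, "0\\.8500")
  ## re-rendering is byte-identical
  d2 <- withr::local_tempdir()
  paths2 <- renderReport(p, d2, prefix = "t")
  expect_identical(readLines(paths2[["tsv"]]), tsv)
  expect_identical(readLines(paths2[["html"]]),
                   readLines(paths[["html"]]))
  ## HTML carries the flag colors inline and nothing external
  html <- paste(readLines(paths[["html"]]), collapse = "\n")
  expect_match(html, "#1a9850|#91cf60|#fee08b|#fc8d59|#d73027")
  expect_no_match(html, "http")
})

test_that("count formatting uses thousands separators", {
  p <- buildMetricPanel(list(R = 31000000, P = 12000))
  d <- withr::local_tempdir()
  tsv <- readLines(renderReport(p, d)[["tsv"]])
  expect_match(grep("Raw reads", tsv, value = TRUE), "31,000,000")
  expect_match(grep("^Peaks", tsv, value = TRUE), "12,000")
})
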