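testingCM <- function() confusionMatrixFromCounts(tp = 52L, fp = 2L,
                                                  tn = 37L, fn = 1L)

test_that("confusion matrix counts match a brute-force pairwise oracle", {
  withSeed(10L, {
    true <- sample(c("cd41_pos", "cd41_neg"), 1000L, replace = TRUE)
    pred <- sample(c("cd41_pos", "cd41_neg"), 1000L, replace = TRUE)
  })
  cm <- confusionMatrix(true, pred, "cd41_pos")
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(true)) {
    if (true[i] == "cd41_pos" && pred[i] == "cd41_pos") tp <- tp + 1L
    if (true[i] != "cd41_pos" && pred[i] == "cd41_pos") fp <- fp + 1L
    if (true[i] != "cd41_pos" && pred[i] != "cd41_pos") tn <- tn + 1L
    if (true[i] == "cd41_pos" && pred[i] != "cd41_pos") fn <- fn + 1L
  }
  expect_equal(c(cm@tp, cm@fp, cm@tn, cm@fn), c(tp, fp, tn, fn))
  expect_error(confusionMatrix(true[1:5], pred[1:4], "cd41_pos"), "length")
  expect_error(confusionMatrix(c("a", "b", "c"), c("a", "b", "c"), "a"),
               "two classes")
})

test_that("perfect and degenerate predictions count correctly", {
  perfect <- confusionMatrix(rep(c("p", "n"), each = 10L),
                             rep(c("p", "n"), each = 10L), "p")
  expect_equal(c(perfect@tp, perfect@tn, perfect@fp, perfect@fn),
               c(10L, 10L, 0L, 0L))
  allPos <- confusionMatrix(rep(c("p", "n"), c(3L, 4L)), rep("p", 7L), "p")
  expect_equal(c(allPos@tp, allPos@fp, allPos@tn, allPos@fn),
               c(3L, 4L, 0L, 0L))
})

test_that("the published-style worked example reproduces every statistic", {
  cm <- testingCM()
  expect_equal(halfUp(accuracyPct(cm), 2), 96.74)
  expect_equal(halfUp(recallPct(cm), 2), 98.11)
  expect_equal(halfUp(precisionPct(cm), 2), 96.30)
  rep <- metricsReport(cm)
  expect_equal(rep@accuracy, 96.74)
  # misclassification rates from the row-normalized (recall) view
  expect_equal(halfUp(100 * rep@rowNorm["cd41_pos", "cd41_neg"], 2), 1.89)
  expect_equal(halfUp(100 * rep@rowNorm["cd41_neg", "cd41_pos"], 2), 5.13)
  # negative-class recall at table precision
  expect_equal(rep@table$recall[rep@table$class == "cd41_neg"], 94.9)
  expect_equal(rep@table$support[1:2], c(53L, 39L))
})

test_that("accuracy extremes behave", {
  expect_equal(accuracyPct(confusionMatrixFromCounts(10L, 0L, 10L, 0L)), 100)
  expect_equal(accuracyPct(confusionMatrixFromCounts(0L, 5L, 0L, 5L)), 0)
  expect_error(accuracyPct(confusionMatrixFromCounts(0L, 0L, 0L, 0L)),
               "empty")
})

test_that("F1 is the harmonic mean and reproduces the printed values", {
  expect_equal(halfUp(f1Pct(96.3, 98.1), 1), 97.2)
  expect_equal(halfUp(f1Pct(89.2, 90.4), 1), 89.8)
  expect_equal(f1Pct(100, 100), 100)
  expect_warning(z <- f1Pct(0, 0), "undefined")
  expect_equal(z, 0)
})

test_that("F1 sits below geometric and arithmetic means (1000 random pairs)", {
  withSeed(11L, {
    p <- runif(1000L, 1e-3, 100)
    r <- runif(1000L, 1e-3, 100)
  })
  f1 <- mapply(f1Pct, p, r)
  expect_true(all(f1 <= sqrt(p * r) + 1e-12))
  expect_true(all(f1 <= (p + r) / 2 + 1e-12))
  expect_true(all(f1 >= pmin(p, r) - 1e-12))
})

test_that("support-weighted averages reproduce the printed table rows", {
  expect_equal(halfUp(weightedAverage(c(97.2, 96.1), c(53, 39)), 1), 96.7)
  expect_equal(halfUp(weightedAverage(c(98.1, 97.4), c(54, 38)), 1), 97.8)
  expect_equal(weightedAverage(c(80, 90), c(5, 5)), 85)
  expect_error(weightedAverage(c(1, 2), c(0, 0)), "positive")
})

test_that("accuracy equals support-weighted recall (random matrices)", {
  withSeed(12L, {
    for (k in 1:50) {
      cm <- confusionMatrixFromCounts(sample(1:50, 1L), sample(0:50, 1L),
                                      sample(1:50, 1L), sample(0:50, 1L))
      recPos <- recallPct(cm)
      recNeg <- 100 * cm@tn / (cm@tn + cm@fp)
      sup <- c(cm@tp + cm@fn, cm@tn + cm@fp)
      expect_equal(accuracyPct(cm),
                   weightedAverage(c(recPos, recNeg), sup),
                   tolerance = 1e-12)
    }
  })
})

test_that("normalized views sum to one along the right margins", {
  rep <- metricsReport(testingCM())
  expect_equal(unname(rowSums(rep@rowNorm)), c(1, 1))
  expect_equal(unname(colSums(rep@colNorm)), c(1, 1))
})

test_that("undefined metrics are reported missing, not zero", {
  oneClass <- confusionMatrixFromCounts(0L, 0L, 5L, 3L)
  expect_warning(p <- precisionPct(oneClass), "undefined")
  expect_true(is.na(p))
  rep <- suppressWarnings(metricsReport(oneClass))
  expect_true(is.na(rep@table$precision[1L]))
  expect_true(is.na(rep@table$f1[3L]))
})

test_that("metrics report round-trips losslessly through JSON", {
  rep <- metricsReport(testingCM())
  path <- withr::local_tempfile(fileext = ".json")
  writeMetricsReport(rep, path)
  back <- readMetricsReport(path)
  expect_equal(back@table, rep@table)
  expect_equal(back@accuracy, rep@accuracy)
  expect_equal(back@rowNorm, rep@rowNorm)
})

test_that("half-up rounding follows the table convention", {
  expect_equal(halfUp(96.735, 2), 96.74)
  expect_equal(halfUp(94.85, 1), 94.9)
  expect_equal(halfUp(2.5, 0), 3)
  expect_equal(halfUp(-2.5, 0), -3)
  expect_equal(proportionPct(84, 463), 18)
})
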