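test_that("confusion counts partition the samples", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")], use.names = FALSE),
               c(2, 0, 2, 0))
  cc <- confusionCounts(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(cc$tp + cc$tn, 0)
  cc <- confusionCounts(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")], use.names = FALSE),
               c(1, 1, 1, 1))
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics reproduce a reconstructed reported fold row", {
  # counts recovered by exhaustive search over tp in [0, 920], tn in
  # [0, 1639] to match the published fold-1 individual-VGG row
  m <- computeMetrics(list(tp = 242, fn = 678, tn = 1539, fp = 100))
  expect_equal(roundHalfUp(m$sens), 26.304)
  expect_equal(roundHalfUp(m$spec), 93.899)
  expect_equal(roundHalfUp(m$accuracy), 69.597)
})

test_that("metrics handle perfect, failing and single-class cases", {
  perfect <- computeMetrics(list(tp = 10, fn = 0, tn = 20, fp = 0))
  expect_equal(c(perfect$sens, perfect$spec, perfect$accuracy),
               c(100, 100, 100))
  fail <- computeMetrics(list(tp = 0, fn = 10, tn = 0, fp = 20))
  expect_equal(c(fail$sens, fail$spec, fail$accuracy), c(0, 0, 0))
  onesided <- computeMetrics(list(tp = 5, fn = 5, tn = 0, fp = 0))
  expect_true(is.na(onesided$spec))
  expect_false(is.na(onesided$sens))
})

test_that("accuracy identity holds for arbitrary counts", {
  set.seed(5)
  for (i in 1:50) {
    cnt <- list(tp = sample(0:50, 1), fn = sample(0:50, 1),
                tn = sample(0:50, 1), fp = sample(0:50, 1))
    if (cnt$tp + cnt$fn == 0 || cnt$tn + cnt$fp == 0) next
    m <- computeMetrics(cnt)
    P <- cnt$tp + cnt$fn; N <- cnt$tn + cnt$fp
    expect_equal(m$accuracy, (m$sens * P + m$spec * N) / (P + N),
                 tolerance = 1e-9)
  }
})

test_that("weighted fold average reproduces the published overall rows", {
  rows <- list(list(sens = 26.304, spec = 93.899, accuracy = 69.597),
               list(sens = 77.417, spec = 54.273, accuracy = 68.584))
  avg <- weightedFoldAverage(rows, positives = c(920, 3299),
                             negatives = c(1639, 2036))
  expect_equal(roundHalfUp(avg$sens), 66.271)
  expect_equal(roundHalfUp(avg$spec), 71.946)
  expect_equal(roundHalfUp(avg$accuracy), 68.912)
  # identical rows are a fixed point under any weights
  same <- list(list(sens = 40, spec = 60, accuracy = 52),
               list(sens = 40, spec = 60, accuracy = 52))
  avg <- weightedFoldAverage(same, c(10, 99), c(5, 42))
  expect_equal(c(avg$sens, avg$spec, avg$accuracy), c(40, 60, 52))
  expect_error(weightedFoldAverage(rows, c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("weighted fold average equals metrics of the pooled counts", {
  set.seed(9)
  for (i in 1:20) {
    c1 <- list(tp = sample(1:40, 1), fn = sample(1:40, 1),
               tn = sample(1:40, 1), fp = sample(1:40, 1))
    c2 <- list(tp = sample(1:40, 1), fn = sample(1:40, 1),
               tn = sample(1:40, 1), fp = sample(1:40, 1))
    avg <- weightedFoldAverage(list(computeMetrics(c1), computeMetrics(c2)),
                               positives = c(c1$tp + c1$fn, c2$tp + c2$fn),
                               negatives = c(c1$tn + c1$fp, c2$tn + c2$fp))
    pooled <- computeMetrics(list(tp = c1$tp + c2$tp, fn = c1$fn + c2$fn,
                                  tn = c1$tn + c2$tn, fp = c1$fp + c2$fp))
    expect_equal(avg$sens, pooled$sens, tolerance = 1e-12)
    expect_equal(avg$spec, pooled$spec, tolerance = 1e-12)
    expect_equal(avg$accuracy, pooled$accuracy, tolerance = 1e-12)
  }
})

test_that("ROC sweeps thresholds with GAR = 100 - FRR against FAR", {
  # perfectly separated scores attain (far 0, gar 100)
  rc <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(rc$far == 0 & rc$gar == 100))

  # hand-checked operating point: threshold 0.9 accepts only the top frame
  rc <- rocCurve(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  expect_true(any(rc$far == 0 & rc$gar == 50))

  # degenerate equal scores: only the two trivial operating points
  rc <- rocCurve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  pts <- unique(rc[, c("far", "gar")])
  expect_equal(nrow(pts), 2)
  expect_true(all(pts$far %in% c(0, 100) & pts$gar %in% c(0, 100)))

  expect_error(rocCurve(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("lowering the threshold never decreases FAR or GAR", {
  set.seed(21)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  rc <- rocCurve(scores, labels)
  ord <- order(rc$threshold, decreasing = TRUE)
  expect_true(all(diff(rc$far[ord]) >= 0))
  expect_true(all(diff(rc$gar[ord]) >= 0))
  expect_true(any(rc$far == 100 & rc$gar == 100))
})

test_that("fold-averaged ROC interpolates onto the fixed FAR grid", {
  rc <- rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  avg <- averageRocCurves(list(rc, rc))
  expect_equal(avg$far, seq(0, 100, by = 1))
  single <- averageRocCurves(list(rc))
  expect_equal(avg$gar, single$gar)
  # midpoint property on synthetic flat curves
  c1 <- structure(data.frame(threshold = NA, far = c(0, 100),
                             gar = c(40, 40)), class = c("RocCurve", "data.frame"))
  c2 <- structure(data.frame(threshold = NA, far = c(0, 100),
                             gar = c(60, 60)), class = c("RocCurve", "data.frame"))
  avg <- averageRocCurves(list(c1, c2))
  expect_equal(avg$gar[avg$far == 10], 50)
})

test_that("accuracy reconstruction from rates matches the pooled definition", {
  # reconstruction from 3-decimal printed rates carries up to 1e-3 of
  # rounding error relative to the count-level accuracy
  expect_lte(abs(accuracyFromRates(26.304, 93.899, 920, 1639) - 69.597),
             1e-3)
  m <- computeMetrics(list(tp = 13, fn = 7, tn = 25, fp = 5))
  expect_equal(accuracyFromRates(m$sens, m$spec, 20, 30), m$accuracy)
})
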