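test_that("confusion counts match hand-picked cases", {
  set.seed(2)
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  cc <- confusionCounts(m, m)
  expect_equal(cc@fp, 0); expect_equal(cc@fn, 0)
  expect_equal(cc@tp, sum(m))
  cc2 <- confusionCounts(1 - m, m)
  expect_equal(cc2@tp, 0); expect_equal(cc2@tn, 0)
  expect_error(confusionCounts(m, m[1:5, ]), "shapes differ")
  expect_error(confusionCounts(m * 0.5, m), "binary")
})

test_that("counts agree exactly with the per-pixel double-loop oracle", {
  set.seed(3)
  for (trial in 1:20) {
    pred <- matrix(rbinom(32 * 32, 1, runif(1, 0.1, 0.9)), 32, 32)
    truth <- matrix(rbinom(32 * 32, 1, runif(1, 0.1, 0.9)), 32, 32)
    roi <- if (trial %% 4 == 0)
      matrix(rbinom(32 * 32, 1, 0.8), 32, 32) else NULL
    cc <- confusionCounts(pred, truth, roi)
    ref <- confusion_oracle(pred, truth, roi)
    expect_identical(c(cc@tp, cc@fp, cc@fn, cc@tn), unname(ref))
    expect_equal(cc@tp + cc@fp + cc@fn + cc@tn,
                 if (is.null(roi)) 1024 else sum(roi))
  }
})

test_that("the five statistics evaluate the defining ratios", {
  cc <- new("ConfusionCounts", tp = 50, fp = 10, fn = 20, tn = 920)
  r <- computeMetrics(cc)
  expect_equal(r@accuracy, 0.97)
  expect_equal(r@precision, 50 / 60)
  expect_equal(r@recall, 50 / 70)
  expect_equal(r@f1, 2 * (50 / 60) * (50 / 70) / (50 / 60 + 50 / 70))
  expect_equal(r@iou, 50 / 80)
  expect_length(r@undefined, 0)
})

test_that("perfect and degenerate predictions follow the conventions", {
  perfect <- computeMetrics(new("ConfusionCounts", tp = 30, fp = 0, fn = 0, tn = 70))
  for (s in c("accuracy", "precision", "recall", "f1", "iou"))
    expect_equal(slot(perfect, s), 1)
  # all-background prediction with vessels present: precision undefined
  empty <- computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 12, tn = 88))
  expect_equal(empty@precision, 0)
  expect_equal(empty@recall, 0)
  expect_equal(empty@f1, 0)
  expect_equal(empty@iou, 0)
  expect_true("precision" %in% empty@undefined)
  expect_error(computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 0, tn = 0)),
               "no evaluated pixels")
})

test_that("f1 and iou satisfy their algebraic identity", {
  set.seed(4)
  for (i in 1:50) {
    cc <- new("ConfusionCounts", tp = rpois(1, 50) + 1, fp = rpois(1, 20),
              fn = rpois(1, 20), tn = rpois(1, 500))
    r <- computeMetrics(cc)
    expect_equal(r@f1, 2 * r@iou / (1 + r@iou), tolerance = 1e-14)
    expect_lte(r@iou, r@f1)
  }
})

test_that("label symmetries hold", {
  set.seed(5)
  pred <- matrix(rbinom(400, 1, 0.4), 20, 20)
  truth <- matrix(rbinom(400, 1, 0.4), 20, 20)
  a <- computeMetrics(confusionCounts(pred, truth))
  b <- computeMetrics(confusionCounts(1 - pred, 1 - truth))
  expect_equal(a@accuracy, b@accuracy)     # accuracy invariant to joint swap
  sw <- computeMetrics(confusionCounts(truth, pred))  # transpose FP <-> FN
  expect_equal(a@precision, sw@recall)
  expect_equal(a@recall, sw@precision)
})

test_that("micro and macro aggregation differ as designed", {
  one <- confusionCounts(matrix(c(1, 0, 1, 1), 2), matrix(c(1, 1, 0, 1), 2))
  single <- aggregateMetrics(list(one), "micro")
  expect_equal(single@f1, aggregateMetrics(list(one), "macro")@f1)
  expect_equal(single@f1, computeMetrics(one)@f1)
  # identical counts: micro = macro
  two <- aggregateMetrics(list(one, one), "micro")
  expect_equal(two@f1, aggregateMetrics(list(one, one), "macro")@f1)
  # one image with 10x the pixels: micro weighs it 10x, macro equally
  small <- new("ConfusionCounts", tp = 8, fp = 2, fn = 0, tn = 90)   # 100 px
  big <- new("ConfusionCounts", tp = 10, fp = 200, fn = 190, tn = 600) # 1000 px
  micro <- aggregateMetrics(list(small, big), "micro")
  macro <- aggregateMetrics(list(small, big), "macro")
  # hand computation on the pooled and per-image counts
  expect_equal(micro@precision, 18 / (18 + 202))
  p_small <- 8 / 10; p_big <- 10 / 210
  expect_equal(macro@precision, (p_small + p_big) / 2)
  expect_false(isTRUE(all.equal(micro@precision, macro@precision)))
  expect_error(aggregateMetrics(list()), "empty")
})
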