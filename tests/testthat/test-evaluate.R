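test_that("confusion counts match trivial and brute-force tallies", {
  truth <- matrix(FALSE, 25, 40)
  truth[1:10, 1:10] <- TRUE            # 100 positives, 900 negatives
  cc <- confusion(truth, truth)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 100L, TN = 900L, FP = 0L, FN = 0L))
  none <- confusion(matrix(FALSE, 25, 40), truth)
  expect_equal(none$FN, 100L)
  set.seed(12)
  p <- random_mask(30, 30, 0.4); t <- random_mask(30, 30, 0.4)
  cc2 <- confusion(p, t)
  brute <- c(0, 0, 0, 0)
  for (i in 1:30) for (j in 1:30) {
    if (p[i, j] && t[i, j]) brute[1] <- brute[1] + 1
    else if (!p[i, j] && !t[i, j]) brute[2] <- brute[2] + 1
    else if (p[i, j]) brute[3] <- brute[3] + 1
    else brute[4] <- brute[4] + 1
  }
  expect_equal(unlist(unclass(cc2)), c(TP = brute[1], TN = brute[2],
                                       FP = brute[3], FN = brute[4]))
  expect_error(confusion(p, t[1:10, ]), "shape")
})

test_that("excluded pixels are left out of the evaluation", {
  p <- random_mask(20, 20, 0.5); t <- random_mask(20, 20, 0.5)
  ex <- matrix(FALSE, 20, 20); ex[, 1:5] <- TRUE
  cc <- confusion(p, t, exclude = ex)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 20L * 15L)
})

test_that("metric formulas evaluate exactly with undefined flagged", {
  m <- seg_metrics(structure(list(TP = 50, TN = 0, FP = 10, FN = 10),
                             class = "confusion_counts"))
  expect_equal(m$dice, 100 / 120)
  expect_equal(m$ppv, 50 / 60)
  perfect <- seg_metrics(structure(list(TP = 10, TN = 90, FP = 0, FN = 0),
                                   class = "confusion_counts"))
  expect_true(all(unlist(unclass(perfect)) == 1))
  degen <- seg_metrics(structure(list(TP = 0, TN = 5, FP = 0, FN = 3),
                                 class = "confusion_counts"))
  expect_true(is.na(degen$ppv))
  expect_false(is.na(degen$npv))
})

test_that("metrics match brute-force tallies on random mask pairs", {
  set.seed(14)
  for (i in 1:25) {
    p <- random_mask(20, 20, runif(1, 0.1, 0.9))
    t <- random_mask(20, 20, runif(1, 0.1, 0.9))
    cc <- confusion(p, t)
    m <- seg_metrics(cc)
    TP <- sum(p & t); TN <- sum(!p & !t); FP <- sum(p & !t); FN <- sum(!p & t)
    expect_equal(m$sensitivity, TP / (TP + FN))
    expect_equal(m$specificity, TN / (TN + FP))
    expect_equal(m$accuracy, (TP + TN) / 400)
    expect_equal(m$dice, 2 * TP / (2 * TP + FP + FN))
    # harmonic-mean identity when PPV and sensitivity are defined
    if (!is.na(m$ppv) && !is.na(m$sensitivity) &&
        (m$ppv + m$sensitivity) > 0)
      expect_equal(m$dice, 2 * m$ppv * m$sensitivity /
                     (m$ppv + m$sensitivity))
  }
})

test_that("cross-validation splits pullbacks 6/2/2 with disjoint tests", {
  ids <- paste0("pb", 1:10)
  folds <- crossval_split(ids, 5, c(0.6, 0.2, 0.2), seed = 3)
  expect_length(folds, 5)
  tests <- c()
  for (f in folds) {
    expect_length(f$train, 6)
    expect_length(f$validation, 2)
    expect_length(f$test, 2)
    # exhaustive id cross-check: no pullback in two sub-groups of one fold
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    tests <- c(tests, f$test)
  }
  expect_length(tests, 10)
  expect_setequal(tests, ids)          # union covers, pairwise disjoint
  expect_identical(folds, crossval_split(ids, 5, seed = 3))
  expect_false(identical(folds, crossval_split(ids, 5, seed = 4)))
  expect_error(crossval_split(ids[1:3], 5), "at least")
  expect_error(crossval_split(ids, 5, c(0.5, 0.1, 0.4)), "fractions")
})

test_that("held-out ensemble evaluation reduces and pools correctly", {
  m <- build_model(tiny_model_config(), input_size = c(32L, 48L), seed = 8)
  frames <- lapply(1:3, function(i) matrix(runif(32 * 48), 32, 48))
  truths <- lapply(1:3, function(i) random_mask(32, 48, 0.3))
  single <- evaluate_heldout(list(m), frames, truths, postprocess = FALSE)
  five <- evaluate_heldout(rep(list(m), 5), frames, truths,
                           postprocess = FALSE)
  expect_identical(unclass(single$counts), unclass(five$counts))
  # pooled counts equal the sum of per-frame counts
  pooled <- Reduce(function(a, b) fibrocap:::add_confusion(a, b),
                   single$per_frame)
  expect_equal(unclass(pooled), unclass(single$counts))
  # and equal direct prediction metrics
  direct <- structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                      class = "confusion_counts")
  for (i in 1:3)
    direct <- fibrocap:::add_confusion(
      direct, confusion(predict_mask(m, frames[[i]]), truths[[i]]))
  expect_equal(unclass(direct), unclass(single$counts))
})
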