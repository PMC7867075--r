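test_that("confusion metrics match closed forms", {
  M <- diag(c(10L, 10L, 10L, 10L))
  rownames(M) <- colnames(M) <- SLEEP_STAGES
  m <- metrics_from_confusion(M)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$f_score, rep(1, 4))

  M2 <- matrix(c(5L, 0L, 5L, 10L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m2 <- metrics_from_confusion(M2)
  expect_equal(m2$per_class$precision, c(0.5, 1))
  expect_equal(m2$per_class$recall, c(1, 2 / 3))
  expect_equal(m2$per_class$f_score, c(2 / 3, 0.8))
  expect_equal(m2$accuracy, 0.75)

  expect_error(metrics_from_confusion(matrix(0L, 2, 2)),
               class = "bcgsleep_undefined_error")
})

test_that("confusion metrics equal a brute-force TP/FP/FN oracle", {
  set.seed(17)
  for (i in 1:50) {
    M <- matrix(rpois(16, 8), 4, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
    m <- metrics_from_confusion(M)
    for (ci in 1:4) {
      tp <- M[ci, ci]
      fp <- sum(M[ci, -ci])
      fn <- sum(M[-ci, ci])
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      expect_equal(m$per_class$precision[ci], p)
      expect_equal(m$per_class$recall[ci], r)
      if (is.finite(p + r) && p + r > 0)
        expect_equal(m$per_class$f_score[ci], 2 * p * r / (p + r))
    }
    expect_equal(m$accuracy, sum(diag(M)) / sum(M))
  }
})

test_that("confusion matrix orientation puts estimation on rows", {
  M <- confusion_matrix(c("WAKE", "WAKE", "REM"), c("WAKE", "REM", "REM"))
  expect_equal(M["WAKE", "REM"], 1L)   # estimated WAKE, correct REM
  expect_equal(M["REM", "WAKE"], 0L)
  expect_equal(sum(M), 3L)
})

test_that("LOSO folds are subject-disjoint and deterministic", {
  hyps <- lapply(1:3, function(i) toy_hypnogram(120, seed = i))
  feats <- Map(function(h, i) toy_features(h, sprintf("S%d", i), seed = i),
               hyps, 1:3)
  rep1 <- loso_evaluate(feats, hyps, grid = tiny_grid(), seed = 3)
  expect_length(rep1$folds, 3)
  expect_equal(sum(rep1$confusion), sum(lengths(hyps)))
  for (f in rep1$folds) expect_equal(sum(f$confusion), 120L)

  rep2 <- loso_evaluate(feats, hyps, grid = tiny_grid(), seed = 3)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_identical(rep1$accuracy_mean, rep2$accuracy_mean)

  # per-fold metrics agree with metrics_from_confusion on the fold matrix
  for (f in rep1$folds) {
    m <- metrics_from_confusion(f$confusion)
    expect_equal(f$accuracy, m$accuracy)
    expect_equal(f$per_class, m$per_class)
  }

  # pooled accuracy is the epoch-weighted combination of fold accuracies
  accs <- vapply(rep1$folds, `[[`, numeric(1), "accuracy")
  ns <- vapply(rep1$folds, `[[`, numeric(1), "n_test")
  expect_equal(rep1$pooled_metrics$accuracy, sum(accs * ns) / sum(ns))

  expect_error(loso_evaluate(feats[1], hyps[1], grid = tiny_grid()),
               class = "bcgsleep_dataset_error")
})

test_that("perfect predictions yield perfect metrics and a diagonal matrix", {
  truth <- unclass(toy_hypnogram(200, seed = 4))
  M <- confusion_matrix(truth, truth)
  expect_true(all(M[upper.tri(M) | lower.tri(M)] == 0))
  m <- metrics_from_confusion(M)
  expect_equal(m$accuracy, 1)

  scores <- sapply(SLEEP_STAGES, function(cl) as.numeric(truth == cl))
  for (cl in unique(truth)) {
    rp <- roc_points(scores[, cl], truth == cl)
    auc <- sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
    expect_equal(auc, 1)
  }
})

test_that("random 4-class predictions sit at chance accuracy", {
  set.seed(19)
  acc <- replicate(100, {
    truth <- sample(SLEEP_STAGES, 400, TRUE)
    pred <- sample(SLEEP_STAGES, 400, TRUE)
    metrics_from_confusion(confusion_matrix(pred, truth))$accuracy
  })
  expect_equal(mean(acc), 0.25, tolerance = 0.03 / 0.25)
})

test_that("feature significance flags injected effects and not null ones", {
  hyps <- lapply(1:2, function(i) toy_hypnogram(300, seed = i))
  feats <- Map(function(h, i) toy_features(h, sprintf("S%d", i), seed = i),
               hyps, 1:2)
  # null feature: identical distribution across all stages
  for (i in 1:2) feats[[i]]$FS <- 1
  res <- suppressWarnings(feature_significance(feats, hyps, seed = 2))
  s1 <- res$step1
  expect_true(s1$significant[s1$feature == "AGM"])
  expect_true(s1$significant[s1$feature == "VGM"])
  expect_false(isTRUE(s1$significant[s1$feature == "FS"]))
  # AJJI separates the three sleep stages strongly in the toy generator
  s2 <- res$step2
  expect_lt(s2$friedman_p[s2$feature == "SAJJI"], 0.05)
  expect_true(all(is.na(s2[s2$feature == "SFS",
                           c("REM_vs_LIGHT", "REM_vs_DEEP", "LIGHT_vs_DEEP")])))

  # a large injected WAKE/SLEEP shift is detected in nearly every seeded draw
  p_hit <- replicate(100, {
    hyp <- toy_hypnogram(200, seed = sample.int(1e6, 1))
    tabs <- list(toy_features(hyp, "S1", seed = sample.int(1e6, 1)))
    r <- suppressWarnings(
      feature_significance(tabs, list(hyp), seed = sample.int(1e6, 1)))
    r$step1$p[r$step1$feature == "AGM"] < 0.01
  })
  expect_gte(mean(p_hit), 0.95)
})

test_that("summary statistics use the population SD and pooled rates", {
  wake2 <- c(33, 74, 95, 53, 31, 52, 32, 74)
  s <- summary_stats(wake2)
  expect_equal(s$mean, 55.5)

  deep3 <- c(150, 197, 98, 138, 129, 279, 171, 119)
  expect_equal(round(summary_stats(deep3)$sd, 1), 53.3)

  expect_equal(summary_stats(rep(4.2, 6))$sd, 0)
  expect_error(summary_stats(numeric(0)), class = "bcgsleep_format_error")

  expect_equal(stage_rate(c(10, 10), c(100, 100)), 10)
})
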