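test_that("sleep-conditional standardization has unit population moments", {
  tab <- toy_features(toy_hypnogram(40), "S1")
  st1 <- c("WAKE", rep("SLEEP", 39))
  tab$AGM[2:3] <- c(1, 3)
  out <- standardize_sleep(tab[1:3, ], st1[1:3])
  expect_equal(out$SAGM, c(-1, 1))           # two-point z-score, pop SD = 1

  out2 <- standardize_sleep(tab, st1)
  expect_equal(nrow(out2), 39L)
  for (col in c("SAGM", "SVGM", "SFS", "SAJJI", "SVJJI", "SHF_TF", "SHF_LF")) {
    expect_equal(mean(out2[[col]]), 0, tolerance = 1e-9)
    expect_equal(mean(out2[[col]]^2), 1, tolerance = 1e-9)
  }

  cons <- tab[1:5, ]
  cons$VGM <- 0.5
  expect_warning(out3 <- standardize_sleep(cons, rep("SLEEP", 5)),
                 class = "bcgsleep_warning")
  expect_equal(out3$SVGM, rep(0, 5))

  expect_error(standardize_sleep(tab[1:3, ], c("WAKE", "WAKE", "SLEEP")),
               class = "bcgsleep_standardization_error")
})

test_that("sleep elapsed time follows the onset formula", {
  st <- c(rep("SLEEP", 121))
  expect_equal(sleep_elapsed_time(st)[121], 60)
  expect_equal(sleep_elapsed_time(st)[1], 0)

  st2 <- c(rep("WAKE", 10), rep("SLEEP", 30))
  set.seed(14)
  for (m in sample(0:29, 5)) {
    expect_equal(sleep_elapsed_time(st2)[11 + m], 0.5 * m)
  }
  expect_equal(sleep_elapsed_time(st2)[1:10], rep(0, 10))

  expect_warning(z <- sleep_elapsed_time(rep("WAKE", 5)),
                 class = "bcgsleep_warning")
  expect_equal(z, rep(0, 5))
})

test_that("head rest time matches a scan-back oracle", {
  tab <- toy_features(toy_hypnogram(30), "S1")
  tab$AGM <- rep(0.02, 30)
  st <- rep("SLEEP", 30)
  tab$AGM[6] <- 10                           # movement at epoch index 5
  hrt <- head_rest_time(tab, st, theta = 1)
  expect_equal(hrt[26], 10)                  # epoch 25, 20 epochs later
  expect_equal(hrt[6], 0)                    # movement in current epoch

  set.seed(15)
  tab2 <- toy_features(toy_hypnogram(80), "S2")
  st2 <- sample(c("WAKE", "SLEEP"), 80, TRUE, prob = c(0.2, 0.8))
  theta <- stats::median(tab2$AGM[st2 == "SLEEP"]) +
    3 * stats::mad(tab2$AGM[st2 == "SLEEP"])
  hrt2 <- head_rest_time(tab2, st2)
  oracle <- vapply(seq_len(80), function(k) {
    j <- k
    while (j >= 1 && !(tab2$AGM[j] > theta || st2[j] == "WAKE")) j <- j - 1
    if (j < 1) 0 else 0.5 * (k - j)
  }, numeric(1))
  expect_equal(hrt2, oracle)
})

test_that("the stager separates a linearly separable toy and logs the grid", {
  hyps <- lapply(1:3, function(i) toy_hypnogram(150, seed = i))
  feats <- Map(function(h, i) toy_features(h, sprintf("S%d", i), seed = i),
               hyps, 1:3)
  model <- fit_stager(feats, hyps, grid = hyper_grid(), seed = 5)

  # grid search evaluated exactly the printed 2 x 10 x 10 candidates per step
  expect_equal(nrow(model$grid_log$step1), 200L)
  expect_equal(nrow(unique(model$grid_log$step1)), 200L)
  expect_equal(nrow(model$grid_log$step2), 200L)

  # step-1 training accuracy is perfect on separable data
  pred <- predict_stager(model, feats[[1]])
  truth1 <- ifelse(unclass(hyps[[1]]) == "WAKE", "WAKE", "SLEEP")
  expect_equal(pred$step1$labels, truth1)

  # merged output keeps WAKE exactly where step 1 put it
  expect_equal(which(pred$labels == "WAKE"),
               which(pred$step1$labels == "WAKE"))

  # determinism: identical refit and identical predictions
  model2 <- fit_stager(feats, hyps, grid = hyper_grid(), seed = 5)
  pred2 <- predict_stager(model2, feats[[1]])
  expect_identical(pred$labels, pred2$labels)
  expect_identical(model$params, model2$params)

  # 4-class toy accuracy is far above the majority baseline
  acc <- mean(pred$labels == unclass(hyps[[1]]))
  base <- max(table(unclass(hyps[[1]]))) / length(hyps[[1]])
  expect_gt(acc, base + 0.1)
})

test_that("shuffled labels drive cross-validated macro F to chance", {
  set.seed(30)
  n <- 100
  x <- data.frame(AGM = c(rnorm(n, 0), rnorm(n, 3)))
  subj <- rep(c("A", "B"), each = n)
  fscores <- replicate(50, {
    y <- sample(rep(c("WAKE", "SLEEP"), n))   # balanced, shuffled
    f <- numeric(2)
    for (i in 1:2) {
      test <- subj == c("A", "B")[i]
      m <- rf_fit(x[!test, , drop = FALSE], y[!test], "gini", 5, 5, seed = i)
      f[i] <- macro_f(rf_predict(m, x[test, , drop = FALSE]), y[test])
    }
    mean(f)
  })
  expect_lte(mean(fscores), 0.6)
})

test_that("an all-WAKE first step short-circuits the second step", {
  hyps <- lapply(1:2, function(i) toy_hypnogram(100, seed = i))
  feats <- Map(function(h, i) toy_features(h, sprintf("S%d", i), seed = i),
               hyps, 1:2)
  model <- fit_stager(feats, hyps, grid = tiny_grid(), seed = 2)
  wake_tab <- toy_features(new_hypnogram(rep("WAKE", 50)), "S9", seed = 9)
  pred <- predict_stager(model, wake_tab)
  expect_true(all(pred$labels == "WAKE"))
  expect_equal(rowSums(pred$scores), rep(1, 50), tolerance = 1e-12)
})

test_that("prediction validates the feature manifest", {
  hyps <- lapply(1:2, function(i) toy_hypnogram(100, seed = i))
  feats <- Map(function(h, i) toy_features(h, sprintf("S%d", i), seed = i),
               hyps, 1:2)
  model <- fit_stager(feats, hyps, grid = tiny_grid(), seed = 2)
  broken <- feats[[1]]
  broken$AGM <- NULL
  expect_error(predict_stager(model, broken), class = "bcgsleep_manifest_error")
  expect_error(fit_stager(feats[1], hyps[1], grid = tiny_grid()),
               class = "bcgsleep_fit_error")
})

test_that("model bundles round-trip through disk", {
  hyps <- lapply(1:2, function(i) toy_hypnogram(100, seed = i))
  feats <- Map(function(h, i) toy_features(h, sprintf("S%d", i), seed = i),
               hyps, 1:2)
  model <- fit_stager(feats, hyps, grid = tiny_grid(), seed = 2)
  dir <- withr::local_tempdir()
  save_stager(model, dir)
  expect_true(file.exists(file.path(dir, "stager.yaml")))
  back <- load_stager(dir)
  p1 <- predict_stager(model, feats[[1]])
  p2 <- predict_stager(back, feats[[1]])
  expect_identical(p1$labels, p2$labels)
})

test_that("the rpart-backed forest agrees with an established forest", {
  skip_if_not_installed("randomForest")
  set.seed(40)
  n <- 300
  x <- data.frame(a = c(rnorm(n, 0), rnorm(n, 3)),
                  b = c(rnorm(n, 0), rnorm(n, -2)))
  y <- rep(c("P", "Q"), each = n)
  test_idx <- sample(2 * n, 200)
  m1 <- rf_fit(x[-test_idx, ], y[-test_idx], "gini", depth = 6, ntrees = 10,
               seed = 1)
  acc1 <- mean(rf_predict(m1, x[test_idx, ]) == y[test_idx])
  m2 <- randomForest::randomForest(x[-test_idx, ], factor(y[-test_idx]),
                                   ntree = 10)
  acc2 <- mean(as.character(predict(m2, x[test_idx, ])) == y[test_idx])
  expect_gt(acc1, 0.85)
  expect_lt(abs(acc1 - acc2), 0.1)
})
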