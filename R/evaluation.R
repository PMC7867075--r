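# Leave-one-subject-out evaluation, metrics, ROC/AUC, feature significance
# and printed-table summary statistics.

#' Confusion matrix with estimation on rows
#'
#' Rows are the estimated labels, columns the correct labels.
#'
#' @param pred,truth character vectors of stage labels.
#' @param labels label order.
#' @return an integer matrix.
#' @export
confusion_matrix <- function(pred, truth, labels = SLEEP_STAGES) {
  tb <- table(factor(pred, levels = labels), factor(truth, levels = labels))
  m <- matrix(as.integer(tb), nrow = length(labels),
              dimnames = list(estimated = labels, correct = labels))
  m
}

#' Per-class precision, recall, F-score and accuracy from a confusion matrix
#'
#' Standard one-vs-rest definitions on a matrix with estimated labels on
#' rows and correct labels on columns; accuracy is trace over total.
#' Precision or recall with a zero denominator is reported as \code{NA}.
#'
#' @param M square nonnegative integer matrix.
#' @return a list with \code{per_class} (data frame of precision, recall,
#'   f_score) and \code{accuracy}.
#' @export
metrics_from_confusion <- function(M) {
  if (any(M < 0) || any(M != round(M)))
    bcg_error("confusion matrix must hold nonnegative integers", "format")
  total <- sum(M)
  if (total == 0) bcg_error("empty confusion matrix", "undefined")
  classes <- rownames(M)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(M)))
  tp <- diag(M)
  prec <- ifelse(rowSums(M) > 0, tp / rowSums(M), NA_real_)
  rec <- ifelse(colSums(M) > 0, tp / colSums(M), NA_real_)
  pr <- prec + rec
  f <- ifelse(!is.na(pr) & pr > 0, 2 * prec * rec / pr, NA_real_)
  list(per_class = data.frame(class = classes, precision = unname(prec),
                              recall = unname(rec), f_score = unname(f)),
       accuracy = sum(tp) / total)
}

# Empirical ROC points (FPR, TPR) for a one-vs-rest score, thresholds swept
# over the observed scores; used for vertical averaging on a fixed grid.
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]
  tpr <- c(0, cumsum(pos) / max(1, sum(positive)))
  fpr <- c(0, cumsum(!pos) / max(1, sum(!positive)))
  list(fpr = fpr, tpr = tpr)
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' Folds are subjects; all nights of the held-out subject form the test
#' set. Each fold trains a fresh two-step stager (nested hyperparameter
#' selection inside the training pool by default; with
#' \code{paper_faithful = TRUE} the grid search is run once on the full
#' dataset and the chosen settings reused in every fold). The report pools
#' a 4x4 confusion matrix (estimated on rows), carries per-fold per-class
#' precision/recall/F and accuracy, and averages one-vs-rest ROC curves
#' vertically on a fixed 101-point FPR grid; AUCs are computed per fold
#' with \pkg{pROC} and averaged.
#'
#' @param features_list list of \code{epoch_features} tables.
#' @param truth_list list of matching hypnograms.
#' @param grid hyperparameter grid.
#' @param seed integer seed.
#' @param paper_faithful reuse one grid search over all subjects (leaks the
#'   test subject into hyperparameter choice; off by default).
#' @return an object of class \code{eval_report}.
#' @export
loso_evaluate <- function(features_list, truth_list, grid = hyper_grid(),
                          seed = 1L, paper_faithful = FALSE) {
  stopifnot(length(features_list) == length(truth_list))
  subjects_rec <- vapply(features_list, function(f) f$subject_id[1], character(1))
  subjects <- unique(subjects_rec)
  if (length(subjects) < 2L)
    bcg_error("evaluation needs at least 2 subjects", "dataset")

  params <- NULL
  if (paper_faithful) {
    full <- fit_stager(features_list, truth_list, grid, seed)
    params <- full$params
  }

  fpr_grid <- seq(0, 1, length.out = 101)
  classes <- SLEEP_STAGES
  folds <- list()
  pooled <- matrix(0L, 4, 4, dimnames = list(estimated = classes,
                                             correct = classes))
  tpr_sum <- matrix(0, length(fpr_grid), length(classes),
                    dimnames = list(NULL, classes))
  auc <- matrix(NA_real_, length(subjects), length(classes),
                dimnames = list(subjects, classes))

  for (si in seq_along(subjects)) {
    s <- subjects[si]
    tr <- subjects_rec != s
    model <- fit_stager(features_list[tr], truth_list[tr], grid, seed,
                        params = params)
    pred_lab <- character(0); pred_scores <- NULL; truth <- character(0)
    for (ri in which(!tr)) {
      al <- align_epochs(features_list[[ri]], truth_list[[ri]])
      pr <- predict_stager(model, al$features)
      pred_lab <- c(pred_lab, pr$labels)
      pred_scores <- rbind(pred_scores, pr$scores)
      truth <- c(truth, unclass(al$hypnogram))
    }
    M <- confusion_matrix(pred_lab, truth)
    pooled <- pooled + M
    mets <- metrics_from_confusion(M)
    for (cl in classes) {
      pos <- truth == cl
      if (any(pos) && any(!pos)) {
        r <- pROC::roc(response = factor(pos, levels = c(FALSE, TRUE)),
                       predictor = pred_scores[, cl], quiet = TRUE,
                       direction = "<", levels = c(FALSE, TRUE))
        auc[si, cl] <- as.numeric(pROC::auc(r))
        rp <- roc_points(pred_scores[, cl], pos)
        tpr_sum[, cl] <- tpr_sum[, cl] +
          stats::approx(rp$fpr, rp$tpr, xout = fpr_grid, ties = max,
                        rule = 2)$y
      }
    }
    folds[[s]] <- list(subject = s, confusion = M,
                       per_class = mets$per_class, accuracy = mets$accuracy,
                       n_test = length(truth), params = model$params)
  }

  acc <- vapply(folds, `[[`, numeric(1), "accuracy")
  structure(list(folds = folds,
                 confusion = pooled,
                 accuracy_mean = mean(acc),
                 accuracy_sd = stats::sd(acc),
                 auc_per_fold = auc,
                 auc_mean = colMeans(auc, na.rm = TRUE),
                 roc_fpr = fpr_grid,
                 roc_tpr = tpr_sum / length(subjects),
                 pooled_metrics = metrics_from_confusion(pooled),
                 seed = seed, paper_faithful = paper_faithful),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d leave-one-subject-out folds\n", length(x$folds)))
  cat(sprintf("  accuracy %.3f +/- %.3f (pooled %.3f)\n", x$accuracy_mean,
              x$accuracy_sd, x$pooled_metrics$accuracy))
  pc <- x$pooled_metrics$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-5s F %.3f  precision %.3f  recall %.3f  AUC %.3f\n",
                pc$class[i], pc$f_score[i], pc$precision[i], pc$recall[i],
                x$auc_mean[pc$class[i]]))
  invisible(x)
}

#' Feature significance tests across sleep stages
#'
#' First-step features (AGM, VGM, FS, AJJI, VJJI): a paired Wilcoxon
#' signed-rank test between \code{n_per_stage} randomly drawn WAKE epochs
#' and \code{n_per_stage} SLEEP epochs. Second-step features: a Friedman
#' test across matched random draws from REM, LIGHT and DEEP; when the
#' Friedman test is significant at 5\%, pairwise Wilcoxon signed-rank tests
#' follow with Bonferroni correction (x3). Sampling is seeded. Comparisons
#' with insufficient epochs are skipped with a notice.
#'
#' @param features_list list of \code{epoch_features} tables.
#' @param truth_list list of matching hypnograms.
#' @param n_per_stage epochs drawn per stage.
#' @param seed RNG seed for the draws.
#' @return a list with data frames \code{step1} and \code{step2}.
#' @export
feature_significance <- function(features_list, truth_list, n_per_stage = 20,
                                 seed = 1L) {
  aligned <- Map(align_epochs, features_list, truth_list)
  feats <- do.call(rbind, lapply(aligned, `[[`, "features"))
  truth <- unlist(lapply(aligned, function(a) unclass(a$hypnogram)))
  set.seed(seed)

  draw <- function(values, lab) {
    idx <- which(truth == lab)
    if (length(idx) < n_per_stage) return(NULL)
    values[sample(idx, n_per_stage)]
  }

  step1 <- data.frame(feature = STEP1_FEATURES, p = NA_real_,
                      skipped = FALSE)
  for (i in seq_along(STEP1_FEATURES)) {
    f <- STEP1_FEATURES[i]
    w <- draw(feats[[f]], "WAKE")
    slp_idx <- which(truth != "WAKE")
    s <- if (length(slp_idx) >= n_per_stage)
      feats[[f]][sample(slp_idx, n_per_stage)] else NULL
    if (is.null(w) || is.null(s)) {
      step1$skipped[i] <- TRUE
      message(sprintf("feature_significance: %s skipped (insufficient epochs)", f))
      next
    }
    step1$p[i] <- stats::wilcox.test(w, s, paired = TRUE, exact = FALSE)$p.value
  }
  step1$significant <- !step1$skipped & step1$p < 0.05

  # second-step features on truth-conditioned standardized tables
  tab2 <- do.call(rbind, lapply(aligned, function(a) {
    st1 <- ifelse(unclass(a$hypnogram) == "WAKE", "WAKE", "SLEEP")
    t2 <- build_step2_features(a$features, st1)
    t2$.stage <- unclass(a$hypnogram)[st1 == "SLEEP"]
    t2
  }))
  stages3 <- c("REM", "LIGHT", "DEEP")
  rows <- lapply(STEP2_FEATURES, function(f) {
    cols <- lapply(stages3, function(st) {
      idx <- which(tab2$.stage == st)
      if (length(idx) < n_per_stage) return(NULL)
      tab2[[f]][sample(idx, n_per_stage)]
    })
    if (any(vapply(cols, is.null, logical(1)))) {
      message(sprintf("feature_significance: %s skipped (insufficient epochs)", f))
      return(data.frame(feature = f, friedman_p = NA_real_,
                        REM_vs_LIGHT = NA_real_, REM_vs_DEEP = NA_real_,
                        LIGHT_vs_DEEP = NA_real_, skipped = TRUE))
    }
    m <- do.call(cbind, cols)
    fp <- stats::friedman.test(m)$p.value
    pw <- rep(NA_real_, 3)
    if (is.finite(fp) && fp < 0.05) {
      pairs <- list(c(1, 2), c(1, 3), c(2, 3))
      raw <- vapply(pairs, function(pr)
        stats::wilcox.test(m[, pr[1]], m[, pr[2]], paired = TRUE,
                           exact = FALSE)$p.value, numeric(1))
      pw <- pmin(raw * 3, 1)   # Bonferroni over the 3 comparisons
    }
    data.frame(feature = f, friedman_p = fp, REM_vs_LIGHT = pw[1],
               REM_vs_DEEP = pw[2], LIGHT_vs_DEEP = pw[3], skipped = FALSE)
  })
  list(step1 = step1, step2 = do.call(rbind, rows))
}

#' Mean, population SD and pooled percentage summaries
#'
#' \code{summary_stats} returns the arithmetic mean and the population SD
#' (divisor n) of a numeric vector, the conventions used for per-subject
#' summary rows in sleep-study tables. \code{stage_rate} gives the pooled
#' percentage of epochs a stage occupies.
#'
#' @param x nonempty numeric vector.
#' @return \code{summary_stats}: list with \code{mean}, \code{sd}, \code{n}.
#' @export
summary_stats <- function(x) {
  if (!length(x)) bcg_error("empty value list", "format")
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)), n = length(x))
}

#' @rdname summary_stats
#' @param stage_epochs epochs in the stage per subject.
#' @param all_epochs total epochs per subject (pooled denominator).
#' @export
stage_rate <- function(stage_epochs, all_epochs) {
  100 * sum(stage_epochs) / sum(all_epochs)
}

#' Summarize a per-subject stage-count table
#'
#' Takes a long table with columns \code{day, subject, stage, epochs} and
#' produces, per day and stage, the across-subject mean and population SD
#' of the epoch counts and the pooled percentage rate (stage epochs over
#' all epochs of that day). Values are full precision; rounding is left to
#' report rendering.
#'
#' @param counts data frame with columns \code{day, subject, stage, epochs}.
#' @return data frame with columns \code{day, stage, mean, sd, rate}.
#' @export
summarize_stage_table <- function(counts) {
  out <- list()
  for (d in unique(counts$day)) {
    cd <- counts[counts$day == d, ]
    tot <- sum(cd$epochs)
    for (st in unique(cd$stage)) {
      v <- cd$epochs[cd$stage == st]
      ss <- summary_stats(v)
      out[[length(out) + 1L]] <- data.frame(day = d, stage = st,
                                            mean = ss$mean, sd = ss$sd,
                                            rate = 100 * sum(v) / tot)
    }
  }
  do.call(rbind, out)
}
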