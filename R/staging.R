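# Two-step sleep staging.
#
# Step 1 labels every 30-s epoch WAKE or SLEEP from the raw epoch features
# (AGM, VGM, FS, AJJI, VJJI). Step 2 classifies the SLEEP epochs into
# REM/LIGHT/DEEP from the same features z-scored per recording over SLEEP
# epochs only (WAKE epochs carry gross movements orders of magnitude larger
# and would dominate the standardization), the standardized band-power
# ratios, the sleep elapsed time (SET) and the head rest time (HRT).

#' Sleep-conditional standardization of epoch features
#'
#' z-scores AGM, VGM, FS, AJJI, VJJI, HF/TF and HF/LF per recording using
#' the mean and population SD computed over SLEEP-labelled epochs only, and
#' drops the WAKE epochs from the returned table. Outputs are renamed with
#' an S prefix (SAGM, ..., SHF_LF). A feature constant across SLEEP epochs
#' (SD = 0) is set to 0 with a warning.
#'
#' @param features an \code{epoch_features} table for one recording.
#' @param step1 character vector of per-epoch labels, \code{"WAKE"} or
#'   \code{"SLEEP"}, one per row of \code{features}.
#' @return a data frame of SLEEP rows with the standardized columns plus
#'   \code{subject_id, night_id, epoch}.
#' @export
standardize_sleep <- function(features, step1) {
  stopifnot(nrow(features) == length(step1))
  sleep <- step1 == "SLEEP"
  if (sum(sleep) < 2L)
    bcg_error("fewer than 2 SLEEP epochs: cannot standardize", "standardization")
  src <- c(AGM = "SAGM", VGM = "SVGM", FS = "SFS", AJJI = "SAJJI",
           VJJI = "SVJJI", HF_TF = "SHF_TF", HF_LF = "SHF_LF")
  out <- features[sleep, c("subject_id", "night_id", "epoch"), drop = FALSE]
  for (col in names(src)) {
    v <- features[[col]][sleep]
    m <- mean(v)
    s <- sqrt(mean(v^2) - m^2)
    if (s == 0) {
      bcg_warn(sprintf("feature %s constant over SLEEP epochs; standardized to 0", col))
      out[[src[[col]]]] <- rep(0, length(v))
    } else {
      out[[src[[col]]]] <- (v - m) / s
    }
  }
  out
}

#' Sleep elapsed time (SET)
#'
#' Minutes since the first SLEEP-labelled epoch: \code{0.5 * (k - k_onset)}
#' for epochs at or after onset, 0 before. With no SLEEP epoch at all, SET
#' is 0 everywhere with a warning.
#'
#' @param step1 per-epoch \code{"WAKE"}/\code{"SLEEP"} labels.
#' @return numeric vector of SET values in minutes.
#' @export
sleep_elapsed_time <- function(step1) {
  onset <- match("SLEEP", step1)
  if (is.na(onset)) {
    bcg_warn("no SLEEP epoch: SET is 0 everywhere")
    return(rep(0, length(step1)))
  }
  k <- seq_along(step1)
  pmax(0, 0.5 * (k - onset))
}

#' Head rest time (HRT)
#'
#' Minutes since the most recent "head event": an epoch whose AGM exceeds
#' the movement threshold \code{theta}, or a WAKE-labelled epoch, whichever
#' is later (the current epoch counts). Captures the drop in head movement
#' that precedes DEEP sleep by about 10 minutes. The default threshold is
#' \code{median + 3 * MAD} of the SLEEP-epoch AGM of the recording.
#'
#' @param features an \code{epoch_features} table for one recording.
#' @param step1 per-epoch \code{"WAKE"}/\code{"SLEEP"} labels.
#' @param theta movement threshold on AGM (m/s^2); \code{NULL} for the
#'   default per-recording policy.
#' @return numeric vector of HRT values in minutes (0 when no event precedes).
#' @export
head_rest_time <- function(features, step1, theta = NULL) {
  agm <- features$AGM
  stopifnot(length(agm) == length(step1))
  if (is.null(theta)) {
    sl <- agm[step1 == "SLEEP"]
    theta <- if (length(sl)) stats::median(sl) + 3 * stats::mad(sl) else Inf
  }
  event <- agm > theta | step1 == "WAKE"
  k <- seq_along(step1)
  last_event <- cummax(ifelse(event, k, 0L))
  ifelse(last_event == 0L, 0, 0.5 * (k - last_event))
}

# Assemble the full step-2 feature table for one recording from step-1
# labels (truth-derived at training time, predicted at inference).
build_step2_features <- function(features, step1, theta = NULL) {
  tab <- standardize_sleep(features, step1)
  set_all <- sleep_elapsed_time(step1)
  hrt_all <- head_rest_time(features, step1, theta)
  sleep <- step1 == "SLEEP"
  tab$SET <- set_all[sleep]
  tab$HRT <- hrt_all[sleep]
  tab
}

#' Hyperparameter grid for the forest search
#'
#' Default grid: split criterion gini or entropy, tree depth 1--10 and
#' number of trees 1--10 (200 candidates per classifier step).
#'
#' @param criterion,depth,n_trees candidate values.
#' @return a data frame with one row per candidate.
#' @export
hyper_grid <- function(criterion = c("gini", "entropy"), depth = 1:10,
                       n_trees = 1:10) {
  expand.grid(criterion = criterion, depth = depth, n_trees = n_trees,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Macro F-score over the classes present in `truth`.
macro_f <- function(pred, truth, classes = sort(unique(truth))) {
  f <- vapply(classes, function(c) {
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- sum(pred != c & truth == c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(f)
}

# Leave-one-subject-out grid search for a single classifier step.
# Forests of every size share trees: for each (criterion, depth) one forest
# with max(n_trees) trees is fitted per fold and evaluated at cumulative
# sizes, which is identical to fitting each size separately because tree
# seeds derive from the forest seed per tree. Ties are broken by smaller
# depth, then fewer trees, then gini.
grid_search <- function(xs, ys, subjects, grid, seed) {
  cd <- unique(grid[, c("criterion", "depth")])
  sizes <- sort(unique(grid$n_trees))
  kmax <- max(sizes)
  scores <- array(0, dim = c(nrow(cd), length(sizes)))
  folds <- unique(subjects)
  for (fi in seq_along(folds)) {
    test <- subjects == folds[fi]
    xtr <- xs[!test, , drop = FALSE]; ytr <- ys[!test]
    xte <- xs[test, , drop = FALSE];  yte <- ys[test]
    for (ci in seq_len(nrow(cd))) {
      fit <- rf_fit(xtr, ytr, criterion = cd$criterion[ci],
                    depth = cd$depth[ci], ntrees = kmax,
                    seed = tree_seed(seed, ci * 101 + fi))
      cube <- rf_prob_cube(fit, xte)
      acc <- matrix(0, nrow(xte), length(fit$levels))
      kpos <- 0L
      for (k in seq_len(kmax)) {
        acc <- acc + matrix(cube[, , k], nrow = nrow(xte))
        if (k %in% sizes) {
          kpos <- kpos + 1L
          pred <- fit$levels[max.col(acc, ties.method = "first")]
          scores[ci, kpos] <- scores[ci, kpos] + macro_f(pred, yte)
        }
      }
    }
  }
  scores <- scores / length(folds)
  log <- data.frame(criterion = rep(cd$criterion, times = length(sizes)),
                    depth = rep(cd$depth, times = length(sizes)),
                    n_trees = rep(sizes, each = nrow(cd)),
                    macro_f = as.vector(scores))
  ord <- order(-log$macro_f, log$depth, log$n_trees,
               match(log$criterion, c("gini", "entropy")))
  list(best = log[ord[1], , drop = FALSE], log = log)
}

#' Fit the two-step sleep stager
#'
#' Trains both classifier steps on a pool of recordings with reference
#' hypnograms. Hyperparameters (split criterion, depth, number of trees)
#' are selected per step by leave-one-subject-out cross-validation inside
#' the training pool, maximizing the macro F-score; final forests are refit
#' on the full pool with the chosen settings and a fixed seed. Step-2
#' training uses truth-SLEEP epochs with standardization, SET and HRT
#' computed per recording from the truth labels.
#'
#' @param features_list list of \code{epoch_features} tables, one per
#'   recording.
#' @param truth_list list of matching hypnograms.
#' @param grid candidate grid, see \code{\link{hyper_grid}}.
#' @param seed integer seed controlling all forest randomness.
#' @param params optional list \code{list(step1 =, step2 =)} of
#'   pre-selected hyperparameter rows; skips the grid search.
#' @return an object of class \code{trained_stager}.
#' @export
fit_stager <- function(features_list, truth_list, grid = hyper_grid(),
                       seed = 1L, params = NULL) {
  stopifnot(length(features_list) == length(truth_list))
  aligned <- Map(align_epochs, features_list, truth_list)
  features_list <- lapply(aligned, `[[`, "features")
  truth_list <- lapply(aligned, `[[`, "hypnogram")

  subjects_rec <- vapply(features_list, function(f) f$subject_id[1], character(1))
  if (length(unique(subjects_rec)) < 2L)
    bcg_error("training needs at least 2 subjects", "fit")

  # step 1: WAKE vs SLEEP on raw features
  x1 <- do.call(rbind, lapply(features_list, function(f)
    f[, STEP1_FEATURES, drop = FALSE]))
  y1 <- unlist(lapply(truth_list, function(h)
    ifelse(unclass(h) == "WAKE", "WAKE", "SLEEP")))
  s1 <- rep(subjects_rec, vapply(features_list, nrow, integer(1)))
  if (length(unique(y1)) < 2L)
    bcg_error("step-1 labels contain a single class", "fit")

  # step 2: REM/LIGHT/DEEP on truth-conditioned features
  tab2 <- Map(function(f, h) {
    st1 <- ifelse(unclass(h) == "WAKE", "WAKE", "SLEEP")
    t2 <- build_step2_features(f, st1)
    t2$.stage <- unclass(h)[st1 == "SLEEP"]
    t2
  }, features_list, truth_list)
  x2 <- do.call(rbind, lapply(tab2, function(t) t[, STEP2_FEATURES, drop = FALSE]))
  y2 <- unlist(lapply(tab2, `[[`, ".stage"))
  s2 <- unlist(Map(rep, subjects_rec, vapply(tab2, nrow, integer(1))))
  if (length(unique(y2)) < 2L)
    bcg_error("step-2 labels contain a single class", "fit")

  if (is.null(params)) {
    g1 <- grid_search(x1, y1, s1, grid, seed)
    g2 <- grid_search(x2, y2, s2, grid, seed + 1L)
    p1 <- g1$best; p2 <- g2$best
    log1 <- g1$log; log2 <- g2$log
  } else {
    p1 <- params$step1; p2 <- params$step2
    log1 <- log2 <- NULL
  }

  f1 <- rf_fit(x1, y1, criterion = p1$criterion, depth = p1$depth,
               ntrees = p1$n_trees, seed = seed)
  f2 <- rf_fit(x2, y2, criterion = p2$criterion, depth = p2$depth,
               ntrees = p2$n_trees, seed = seed + 1L)

  structure(list(step1 = f1, step2 = f2,
                 params = list(step1 = p1, step2 = p2),
                 grid_log = list(step1 = log1, step2 = log2),
                 manifest = list(step1 = STEP1_FEATURES, step2 = STEP2_FEATURES),
                 seed = seed, epoch_len = 30),
            class = "trained_stager")
}

#' @export
print.trained_stager <- function(x, ...) {
  p1 <- x$params$step1; p2 <- x$params$step2
  cat("<trained_stager> two-step random forest\n")
  cat(sprintf("  step 1 (WAKE/SLEEP):      %s, depth %d, %d trees\n",
              p1$criterion, p1$depth, p1$n_trees))
  cat(sprintf("  step 2 (REM/LIGHT/DEEP):  %s, depth %d, %d trees\n",
              p2$criterion, p2$depth, p2$n_trees))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Predict sleep stages for one recording
#'
#' Step 1 labels every epoch WAKE or SLEEP; step-2 features are then built
#' from the step-1 output (standardization over predicted-SLEEP epochs,
#' SET, HRT) and the SLEEP epochs classified REM/LIGHT/DEEP. The merged
#' 4-class prediction keeps WAKE exactly where step 1 placed it. Per-class
#' scores: WAKE takes the step-1 WAKE probability; the sleep classes share
#' the remainder proportionally to the step-2 probabilities (uniformly for
#' epochs predicted WAKE).
#'
#' @param model a \code{trained_stager}.
#' @param features an \code{epoch_features} table for one recording.
#' @return an object of class \code{stage_prediction}: \code{labels}
#'   (4-class), \code{scores} (n x 4 matrix, rows summing to 1),
#'   \code{step1} (labels and WAKE probability).
#' @export
predict_stager <- function(model, features) {
  miss <- setdiff(model$manifest$step1, names(features))
  if (length(miss))
    bcg_error(paste0("missing feature column(s): ", paste(miss, collapse = ", ")),
              "manifest")
  x1 <- features[, model$manifest$step1, drop = FALSE]
  pr1 <- rf_predict_prob(model$step1, x1)
  p_wake <- pr1[, "WAKE"]
  lab1 <- ifelse(model$step1$levels[max.col(pr1, ties.method = "first")] == "WAKE",
                 "WAKE", "SLEEP")

  n <- nrow(features)
  scores <- matrix(0, n, 4, dimnames = list(NULL, SLEEP_STAGES))
  scores[, "WAKE"] <- p_wake
  labels <- rep("WAKE", n)
  sleep <- lab1 == "SLEEP"
  if (any(sleep)) {
    tab2 <- build_step2_features(features, lab1)
    pr2 <- rf_predict_prob(model$step2, tab2[, model$manifest$step2, drop = FALSE])
    lab2 <- model$step2$levels[max.col(pr2, ties.method = "first")]
    labels[sleep] <- lab2
    for (cl in model$step2$levels)
      scores[sleep, cl] <- (1 - p_wake[sleep]) * pr2[, cl]
    # classes absent from the step-2 forest keep score 0
  }
  if (any(!sleep)) {
    rest <- setdiff(SLEEP_STAGES, "WAKE")
    for (cl in rest)
      scores[!sleep, cl] <- (1 - p_wake[!sleep]) / 3
  }
  structure(list(labels = labels, scores = scores,
                 step1 = list(labels = lab1, p_wake = p_wake)),
            class = "stage_prediction")
}

#' @export
print.stage_prediction <- function(x, ...) {
  tb <- table(factor(x$labels, levels = SLEEP_STAGES))
  cat(sprintf("<stage_prediction> %d epochs: %s\n", length(x$labels),
              paste(names(tb), tb, sep = "=", collapse = " ")))
  invisible(x)
}

#' Save / load a trained stager bundle
#'
#' The bundle directory holds a YAML metadata file (hyperparameters, seed,
#' feature manifest) next to the serialized forests, enough to reproduce
#' predictions exactly.
#'
#' @param model a \code{trained_stager}.
#' @param dir bundle directory (created if needed).
#' @export
save_stager <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "bcgsleep",
               seed = model$seed,
               epoch_len = model$epoch_len,
               manifest = model$manifest,
               params = lapply(model$params, as.list))
  yaml::write_yaml(meta, file.path(dir, "stager.yaml"))
  saveRDS(model, file.path(dir, "stager.rds"))
  invisible(dir)
}

#' @rdname save_stager
#' @export
load_stager <- function(dir) {
  f <- file.path(dir, "stager.rds")
  if (!file.exists(f)) bcg_error(paste0("no stager bundle in ", dir), "format")
  readRDS(f)
}
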