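# Random forest built on rpart trees.
#
# The hyperparameter grid requires both gini and entropy split criteria;
# rpart supplies both ("gini" / "information") for the tree induction, and
# the ensemble adds bootstrap resampling plus a per-tree random feature
# subspace (mtry = floor(sqrt(p))). Remaining tree controls mirror common
# learner defaults: minsplit 2, minbucket 1, cp 0, no surrogates.
# Per-tree seeds are derived from the forest seed, so the first k trees of
# a larger forest are exactly the k-tree forest with the same seed.

tree_seed <- function(seed, b) (abs(seed) + 7919 * b) %% 2147483647

rf_fit <- function(x, y, criterion = c("gini", "entropy"), depth = 10L,
                   ntrees = 10L, seed = 1L, mtry = NULL) {
  criterion <- match.arg(criterion)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    bcg_error("training labels contain a single class", "fit")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  split <- if (criterion == "entropy") "information" else "gini"
  ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                               maxdepth = depth, xval = 0L,
                               maxcompete = 0L, maxsurrogate = 0L)
  n <- nrow(x)
  trees <- vector("list", ntrees)
  for (b in seq_len(ntrees)) {
    set.seed(tree_seed(seed, b))
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(p, mtry))
    yb <- y[rows]
    if (length(unique(yb)) < 2L) {
      trees[[b]] <- list(constant = as.character(yb[1]))
      next
    }
    df <- x[rows, feats, drop = FALSE]
    df$.y <- yb
    trees[[b]] <- rpart::rpart(.y ~ ., data = df, method = "class",
                               parms = list(split = split), control = ctrl)
  }
  structure(list(trees = trees, criterion = criterion, depth = depth,
                 ntrees = ntrees, mtry = mtry, levels = levels(y),
                 features = colnames(x), seed = seed),
            class = "bcg_rf")
}

# Per-tree class-probability array (n x levels x trees); forest predictions
# average probabilities, matching probability-averaging forest convention.
rf_prob_cube <- function(model, newdata) {
  lv <- model$levels
  n <- nrow(newdata)
  cube <- array(0, dim = c(n, length(lv), model$ntrees),
                dimnames = list(NULL, lv, NULL))
  for (b in seq_along(model$trees)) {
    tr <- model$trees[[b]]
    if (!is.null(tr$constant)) {
      cube[, tr$constant, b] <- 1
    } else {
      pr <- predict(tr, newdata = newdata, type = "prob")
      cube[, colnames(pr), b] <- pr
    }
  }
  cube
}

rf_predict_prob <- function(model, newdata, ntrees = NULL) {
  if (is.null(ntrees)) ntrees <- model$ntrees
  cube <- rf_prob_cube(model, newdata)
  rowSums(cube[, , seq_len(ntrees), drop = FALSE], dims = 2) / ntrees
}

rf_predict <- function(model, newdata, ntrees = NULL) {
  pr <- rf_predict_prob(model, newdata, ntrees)
  model$levels[max.col(pr, ties.method = "first")]
}
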