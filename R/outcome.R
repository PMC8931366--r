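stratified_folds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Training-fold median imputation for missing feature entries (consistent
# leakage policy with the age-prediction models).
impute_median <- function(X, train_idx) {
  X <- as.matrix(X)
  med <- apply(X[train_idx, , drop = FALSE], 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    X[miss, j] <- med[j]
  }
  X
}

fold_auc <- function(obs, score) {
  if (length(unique(obs)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(obs, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Random-forest hyperparameter tuning by random search
#'
#' Draws `n_draws` random (mtry, ntree, nodesize) triples with mtry in
#' [1, p], ntree in \{250, ..., 2000\} and nodesize in [1, 20], and selects
#' the triple maximizing mean AUC over `folds`-fold stratified
#' cross-validation.
#'
#' @param features matrix/data.frame of predictors (NAs allowed; median-
#'   imputed inside training folds).
#' @param outcome binary (0/1 or logical) outcome with both classes present.
#' @param seed integer seed.
#' @param n_draws search budget (default 50).
#' @param folds cross-validation folds (default 5).
#' @return list with `mtry`, `ntree`, `nodesize`, `cv_auc`, and the full
#'   `search` table.
#' @export
rf_tune <- function(features, outcome, seed = 1L, n_draws = 50L, folds = 5L) {
  X <- as.matrix(features)
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) stopf("outcome must have both classes")
  p <- ncol(X)
  with_seed(seed, {
    search <- data.frame(
      mtry = sample.int(p, n_draws, replace = TRUE),
      ntree = sample(250:2000, n_draws, replace = TRUE),
      nodesize = sample.int(20, n_draws, replace = TRUE))
    fold <- stratified_folds(y, folds)
    search$auc <- vapply(seq_len(n_draws), function(d) {
      aucs <- vapply(seq_len(max(fold)), function(f) {
        tr <- fold != f
        Xi <- impute_median(X, which(tr))
        rf <- randomForest::randomForest(
          Xi[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
          mtry = search$mtry[d], ntree = search$ntree[d],
          nodesize = search$nodesize[d])
        sc <- predict(rf, Xi[!tr, , drop = FALSE], type = "prob")[, "1"]
        fold_auc(y[!tr], sc)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(search$auc)
    list(mtry = search$mtry[best], ntree = search$ntree[best],
         nodesize = search$nodesize[best], cv_auc = search$auc[best],
         search = search)
  })
}

#' Cross-validated AUC evaluation of a random-forest classifier
#'
#' Evaluates a tuned random forest with `folds`-fold (default 20) stratified
#' cross-validation: out-of-fold probability scores give one AUC per fold,
#' reported as mean and standard error of the mean. Folds that end up with
#' one outcome class are merged into the next fold. Also fits the forest on
#' the full data for permutation variable importances.
#'
#' @param features matrix/data.frame of predictors (NAs median-imputed
#'   inside training folds).
#' @param outcome binary outcome.
#' @param params list with `mtry`, `ntree`, `nodesize` (from [rf_tune()]).
#' @param seed integer seed.
#' @param folds evaluation folds (default 20).
#' @param pooled also compute a single AUC over the pooled out-of-fold
#'   scores (default TRUE; reported alongside the per-fold mean).
#' @return `codevel_rf_eval`: list with `fold_auc` (vector), `mean_auc`,
#'   `se_auc`, `pooled_auc`, `importance`, `model` (full-data forest),
#'   `params`, `scores` (out-of-fold probabilities).
#' @export
rf_evaluate <- function(features, outcome, params, seed = 1L, folds = 20L,
                        pooled = TRUE) {
  X <- as.matrix(features)
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) stopf("outcome must have both classes")
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    # merge single-class folds into the neighbouring fold
    repeat {
      bad <- which(vapply(seq_len(max(fold)), function(f)
        length(unique(y[fold == f])) < 2 && any(fold == f), logical(1)))
      if (length(bad) == 0) break
      f <- bad[1]
      nb <- if (f < max(fold)) f + 1 else f - 1
      fold[fold == f] <- nb
      fold[fold > f] <- fold[fold > f] - 1
    }
    scores <- rep(NA_real_, length(y))
    aucs <- vapply(seq_len(max(fold)), function(f) {
      tr <- fold != f
      Xi <- impute_median(X, which(tr))
      rf <- randomForest::randomForest(
        Xi[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
        mtry = params$mtry, ntree = params$ntree, nodesize = params$nodesize)
      sc <- predict(rf, Xi[!tr, , drop = FALSE], type = "prob")[, "1"]
      scores[which(!tr)] <<- sc
      fold_auc(y[!tr], sc)
    }, numeric(1))
    Xi_full <- impute_median(X, seq_len(nrow(X)))
    full <- randomForest::randomForest(
      Xi_full, factor(y, levels = c(0, 1)), mtry = params$mtry,
      ntree = params$ntree, nodesize = params$nodesize, importance = TRUE)
    structure(list(
      fold_auc = aucs, mean_auc = mean(aucs, na.rm = TRUE),
      se_auc = sd(aucs, na.rm = TRUE) / sqrt(sum(is.finite(aucs))),
      pooled_auc = if (pooled) fold_auc(y, scores) else NA_real_,
      importance = randomForest::importance(full), model = full,
      params = params, scores = scores, n_folds = max(fold)
    ), class = "codevel_rf_eval")
  })
}

#' @export
print.codevel_rf_eval <- function(x, ...) {
  cat(sprintf(
    "Random-forest evaluation: %d-fold CV AUC = %.3f +/- %.3f (SEM); pooled %.3f\n",
    x$n_folds, x$mean_auc, x$se_auc, x$pooled_auc))
  cat(sprintf("  mtry = %d, ntree = %d, nodesize = %d\n",
              x$params$mtry, x$params$ntree, x$params$nodesize))
  invisible(x)
}

#' Two-feature partial dependence surface
#'
#' Average model prediction over the observed data with a named feature
#' pair clamped to a grid: for each grid point, every row's pair is set to
#' the point and the mean predicted outcome probability is recorded.
#' Grid points outside the observed feature range are flagged as
#' extrapolation with a warning.
#'
#' @param model a fitted `randomForest` (e.g. `$model` of
#'   [rf_evaluate()]) or any object with a prob-type `predict` method.
#' @param features the feature matrix the model was trained on (NAs
#'   median-imputed).
#' @param feature_pair character vector of two column names.
#' @param grid_n grid points per axis (default 20), or a list of two
#'   numeric vectors giving the grid explicitly.
#' @return data.frame with columns (feature 1 value, feature 2 value,
#'   `prob`), one row per grid point.
#' @export
partial_dependence <- function(model, features, feature_pair, grid_n = 20L) {
  X <- impute_median(as.matrix(features), seq_len(nrow(features)))
  if (!all(feature_pair %in% colnames(X))) {
    stopf("feature_pair not found in features")
  }
  rng <- apply(X[, feature_pair, drop = FALSE], 2, range)
  grid <- if (is.list(grid_n)) {
    for (j in 1:2) {
      if (any(grid_n[[j]] < rng[1, j] | grid_n[[j]] > rng[2, j])) {
        warnf("grid extends outside the observed range of %s (extrapolation)",
              feature_pair[j])
      }
    }
    grid_n
  } else {
    lapply(1:2, function(j) seq(rng[1, j], rng[2, j], length.out = grid_n))
  }
  pts <- expand.grid(v1 = grid[[1]], v2 = grid[[2]])
  pts$prob <- vapply(seq_len(nrow(pts)), function(i) {
    Xi <- X
    Xi[, feature_pair[1]] <- pts$v1[i]
    Xi[, feature_pair[2]] <- pts$v2[i]
    pr <- predict(model, Xi, type = "prob")
    mean(pr[, "1"])
  }, numeric(1))
  names(pts)[1:2] <- feature_pair
  pts
}
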