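#' Assemble feature blocks for postmenstrual-age prediction
#'
#' Builds the per-sample feature table for one system. The microbiome system
#' uses nasal and rectal relative abundances as two blocks keyed by
#' (subject, day of life); the immune system uses the Tphe and ICS
#' population relative abundances as two blocks keyed by (subject,
#' timepoint). Samples at or beyond `max_dol` days of life are excluded and
#' taxa present in fewer than `min_taxa_prevalence` of a block's samples are
#' removed. Missingness occurs at whole-block granularity (e.g. a nasal-only
#' day carries an all-`NA` rectal block); z-scoring and imputation are
#' deferred to the training folds of [tune_and_predict()].
#'
#' @param cohort a `codevel_cohort` (or any list with compatible `samples` /
#'   `features` elements).
#' @param system `"microbiome"` or `"immune"`.
#' @param max_dol exclusive day-of-life cutoff (default 450).
#' @param min_taxa_prevalence per-block prevalence filter (default 0.03).
#' @return `codevel_features`: list with `blocks` (named list of row-aligned
#'   matrices containing `NA` rows for missing blocks), `subject`,
#'   `pma_days`, `row_key`, `system`.
#' @export
assemble_features <- function(cohort, system = c("microbiome", "immune"),
                              max_dol = 450, min_taxa_prevalence = 0.03) {
  system <- match.arg(system)
  sites <- if (system == "microbiome") c("nasal", "rectal") else
    c("immune_tphe", "immune_ics")
  keyof <- function(s) paste(s$subject_id,
                             if (system == "microbiome") s$dol else s$timepoint,
                             sep = "|")
  smp <- cohort$samples[cohort$samples$site %in% sites &
                          cohort$samples$dol < max_dol, ]
  if (nrow(smp) == 0) stopf("no %s samples before DOL %d", system, max_dol)
  smp$key <- keyof(smp)
  keys <- unique(smp$key)
  meta <- smp[!duplicated(smp$key), c("subject_id", "pma_days", "key")]
  rownames(meta) <- meta$key

  blocks <- list()
  for (site in sites) {
    ss <- smp[smp$site == site, ]
    feat <- cohort$features[[site]][ss$sample_id, , drop = FALSE]
    rs <- rowSums(feat)
    prop <- feat / ifelse(rs > 0, rs, 1)
    keep <- colMeans(prop > 0) >= min_taxa_prevalence
    if (!any(keep)) stopf("no %s features pass the prevalence filter", site)
    prop <- prop[, keep, drop = FALSE]
    m <- matrix(NA_real_, length(keys), ncol(prop),
                dimnames = list(keys, paste(site, colnames(prop), sep = ".")))
    m[ss$key, ] <- prop
    blocks[[site]] <- m
  }
  structure(list(blocks = blocks, subject = meta[keys, "subject_id"],
                 pma_days = meta[keys, "pma_days"], row_key = keys,
                 system = system), class = "codevel_features")
}

#' @export
print.codevel_features <- function(x, ...) {
  cat(sprintf("%s feature set: %d samples, %d subjects, blocks: %s\n",
              x$system, length(x$row_key), length(unique(x$subject)),
              paste(sprintf("%s(%d)", names(x$blocks),
                            vapply(x$blocks, ncol, 1L)), collapse = ", ")))
  invisible(x)
}

group_folds <- function(subjects, k) {
  sids <- unique(subjects)
  if (length(sids) < k) {
    warnf("fewer subjects (%d) than folds (%d); reducing folds",
          length(sids), k)
    k <- length(sids)
  }
  fold_of <- setNames(rep(seq_len(k), length.out = length(sids)),
                      sample(sids))
  unname(fold_of[subjects])
}

# Training-fold imputation + z-scoring chained in front of the elastic net:
# block-missing rows are filled with training-fold column means, then all
# columns are z-scored with training-fold statistics. A block entirely
# missing from the training fold centres at 0 with unit scale, so imputed
# test values land at the post-z-score centre (flagged via attribute).
prepare_fold <- function(blocks, train_idx) {
  prep_one <- function(m) {
    tr <- m[train_idx, , drop = FALSE]
    mu <- colMeans(tr, na.rm = TRUE)
    allmiss <- !is.finite(mu)
    mu[allmiss] <- 0
    filled <- m
    miss <- is.na(filled[, 1])
    if (any(miss)) {
      filled[miss, ] <- matrix(mu, sum(miss), length(mu), byrow = TRUE)
    }
    ctr <- colMeans(filled[train_idx, , drop = FALSE])
    sc <- apply(filled[train_idx, , drop = FALSE], 2, sd)
    sc[!is.finite(sc) | sc < 1e-12] <- 1
    out <- sweep(sweep(filled, 2, ctr, "-"), 2, sc, "/")
    attr(out, "all_missing_block") <- any(allmiss)
    out
  }
  out <- do.call(cbind, lapply(blocks, prep_one))
  out
}

#' Subject-held-out elastic-net prediction of log2 postmenstrual age
#'
#' Tunes and fits an elastic net predicting log2(PMA in weeks) from the
#' assembled feature blocks, with every fold grouping by subject so that a
#' subject's entire longitudinal record is held out together. Tuning draws
#' `n_draws` (default 50) uniform (alpha, lambda) pairs with alpha in [0, 1]
#' and lambda in [0.001, 0.5] and picks the pair minimizing mean test MSE
#' over 5-fold grouped cross-validation (on the log2 scale); the winner is
#' then refit with 10-fold grouped cross-validation to produce a held-out
#' prediction for every sample. Imputation of block-missing values (by
#' training-fold means) and z-scoring (by training-fold statistics) are
#' chained inside each fold, so no statistic leaks from held-out subjects.
#' R-squared is reported on the back-transformed scale `2^yhat` vs PMA.
#'
#' @param features a `codevel_features` from [assemble_features()].
#' @param seed integer seed (folds and tuning draws).
#' @param n_draws tuning budget (default 50).
#' @param tune_folds,final_folds fold counts (defaults 5 and 10).
#' @param alpha_range,lambda_range tuning ranges.
#' @return `codevel_pma_pred`: list with `predictions` (data.frame: row_key,
#'   subject, pma_days, fold, y, yhat), `alpha`, `lambda`, `r2`
#'   (back-transformed), `r2_log`, `draws` (tuning table), `system`.
#' @export
tune_and_predict <- function(features, seed = 1L, n_draws = 50L,
                             tune_folds = 5L, final_folds = 10L,
                             alpha_range = c(0, 1),
                             lambda_range = c(0.001, 0.5)) {
  stopifnot(inherits(features, "codevel_features"))
  n_subj <- length(unique(features$subject))
  if (n_subj < 20) stopf("need >= 20 subjects (have %d)", n_subj)
  y <- log2(features$pma_days / 7)
  blocks <- features$blocks
  n <- length(y)

  with_seed(seed, {
    draws <- data.frame(alpha = runif(n_draws, alpha_range[1], alpha_range[2]),
                        lambda = runif(n_draws, lambda_range[1],
                                       lambda_range[2]))
    tf <- group_folds(features$subject, tune_folds)
    # fold-wise design matrices are shared across tuning draws
    fold_data <- lapply(seq_len(max(tf)), function(f) {
      X <- prepare_fold(blocks, which(tf != f))
      list(train = which(tf != f), test = which(tf == f), X = X)
    })
    draws$mse <- vapply(seq_len(n_draws), function(d) {
      errs <- vapply(fold_data, function(fd) {
        fit <- glmnet::glmnet(fd$X[fd$train, , drop = FALSE], y[fd$train],
                              alpha = draws$alpha[d], standardize = FALSE,
                              lambda = lambda_path(draws$lambda[d]))
        pred <- predict(fit, fd$X[fd$test, , drop = FALSE],
                        s = draws$lambda[d])
        mean((y[fd$test] - pred)^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- which.min(draws$mse)
    alpha_hat <- draws$alpha[best]
    lambda_hat <- draws$lambda[best]

    ff <- group_folds(features$subject, final_folds)
    yhat <- rep(NA_real_, n)
    for (f in seq_len(max(ff))) {
      tr <- which(ff != f)
      te <- which(ff == f)
      X <- prepare_fold(blocks, tr)
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = alpha_hat,
                            standardize = FALSE,
                            lambda = lambda_path(lambda_hat))
      yhat[te] <- predict(fit, X[te, , drop = FALSE], s = lambda_hat)
    }
    pred <- data.frame(row_key = features$row_key, subject = features$subject,
                       pma_days = features$pma_days, fold = ff, y = y,
                       yhat = yhat, stringsAsFactors = FALSE)
    structure(list(
      predictions = pred, alpha = alpha_hat, lambda = lambda_hat,
      r2 = r_squared(2^yhat, 2^y), r2_log = r_squared(yhat, y),
      draws = draws, system = features$system
    ), class = "codevel_pma_pred")
  })
}

lambda_path <- function(lambda) sort(lambda * c(16, 8, 4, 2, 1),
                                     decreasing = TRUE)

r_squared <- function(pred, obs) 1 - sum((obs - pred)^2) /
  sum((obs - mean(obs))^2)

#' @export
print.codevel_pma_pred <- function(x, ...) {
  cat(sprintf(
    "%s PMA prediction: %d samples, alpha = %.3f, lambda = %.4f\n  held-out R2 = %.3f (back-transformed), %.3f (log2 scale)\n",
    x$system, nrow(x$predictions), x$alpha, x$lambda, x$r2, x$r2_log))
  invisible(x)
}

#' Per-subject maturation trajectories by mixed-model BLUP
#'
#' Regresses the held-out age predictions on true age with correlated
#' random intercepts and slopes per subject:
#' `yhat - log2(37) ~ log2(PMA/37) + (1 + log2(PMA/37) | subject)` (PMA in
#' weeks), fit by REML. Each subject's 37-week intercept `alpha_i` and
#' maturation slope `beta_i` are the fixed effect plus the BLUP of the
#' random effect, with conditional standard errors from the conditional
#' covariance of the random effects. The z-scores subtract the across-
#' subject median and divide by the subject's conditional standard error. A
#' singular random-effect covariance triggers a diagonal-covariance refit,
#' flagged in the result.
#'
#' @param predictions a `codevel_pma_pred`, or a data.frame with columns
#'   `yhat`, `pma_days`, `subject`.
#' @return `codevel_trajectories`: data.frame (subject, alpha, beta,
#'   se_alpha, se_beta, z_alpha, z_beta) with attributes `fixef`,
#'   `singular`, `system`.
#' @export
fit_trajectories <- function(predictions) {
  if (inherits(predictions, "codevel_pma_pred")) {
    sys <- predictions$system
    predictions <- predictions$predictions
  } else {
    sys <- NA_character_
  }
  stopifnot(all(c("yhat", "pma_days", "subject") %in% names(predictions)))
  dat <- data.frame(
    resp = predictions$yhat - log2(37),
    t = log2((predictions$pma_days / 7) / 37),
    subject = predictions$subject)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(resp ~ t + (1 + t | subject), data = dat, REML = TRUE)))
  singular <- lme4::isSingular(fit)
  if (singular) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(resp ~ t + (1 + t || subject), data = dat, REML = TRUE)))
  }
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit, condVar = TRUE)$subject
  pv <- attr(re, "postVar")
  if (is.list(pv)) { # diagonal-covariance refits return a list of blocks
    se_a <- sqrt(pv[[1]][1, 1, ])
    se_b <- sqrt(pv[[2]][1, 1, ])
  } else {
    se_a <- sqrt(pv[1, 1, ])
    se_b <- sqrt(pv[2, 2, ])
  }
  alpha <- fe[1] + re[, 1]
  beta <- fe[2] + re[, 2]
  # a collapsed random-effect variance shrinks every BLUP to the fixed
  # effect (conditional SE 0); those subjects sit at the median, z = 0
  zscore <- function(v, se) ifelse(se > 1e-10, (v - median(v)) / se, 0)
  out <- data.frame(subject = rownames(re), alpha = alpha, beta = beta,
                    se_alpha = se_a, se_beta = se_b,
                    z_alpha = zscore(alpha, se_a),
                    z_beta = zscore(beta, se_b),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fixef") <- fe
  attr(out, "singular") <- singular
  attr(out, "system") <- sys
  class(out) <- c("codevel_trajectories", "data.frame")
  out
}

#' The four-feature Developmental Index
#'
#' Joins the microbiome and immune trajectory z-scores into the per-subject
#' Developmental Index (microbiome intercept z, microbiome slope z, immune
#' intercept z, immune slope z). Subjects present in only one system carry
#' `NA` entries for the other (imputed downstream inside model folds).
#'
#' @param microbiome_traj,immune_traj `codevel_trajectories` for each system.
#' @return data.frame: subject, micro_z_alpha, micro_z_beta, immune_z_alpha,
#'   immune_z_beta.
#' @export
developmental_index <- function(microbiome_traj, immune_traj) {
  if (length(intersect(microbiome_traj$subject, immune_traj$subject)) == 0) {
    stopf("no subjects shared between systems")
  }
  m <- microbiome_traj[, c("subject", "z_alpha", "z_beta")]
  names(m) <- c("subject", "micro_z_alpha", "micro_z_beta")
  i <- immune_traj[, c("subject", "z_alpha", "z_beta")]
  names(i) <- c("subject", "immune_z_alpha", "immune_z_beta")
  out <- merge(m, i, by = "subject", all = TRUE)
  out[order(out$subject), , drop = FALSE]
}
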