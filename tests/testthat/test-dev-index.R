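test_that("feature assembly applies the DOL and prevalence filters", {
  co <- small_cohort(30, seed = 15)
  # push one nasal sample beyond the DOL window
  co$samples$dol[co$samples$site == "nasal"][1] <- 460L
  fb <- assemble_features(co, "microbiome", max_dol = 450)
  moved <- co$samples$sample_id[co$samples$site == "nasal"][1]
  expect_false(any(grepl(moved, fb$row_key)))
  # a 2%-prevalence taxon is removed
  nas <- co$features$nasal
  rare <- colMeans(nas > 0) < 0.03
  if (!any(rare)) {
    co$features$nasal[, 1] <- 0L
    co$features$nasal[1, 1] <- 5L
    fb2 <- assemble_features(co, "microbiome")
    expect_false(paste0("nasal.", colnames(nas)[1]) %in%
                   colnames(fb2$blocks$nasal))
  }
  # immune assembly keys by timepoint, block missingness row-wise
  fbi <- assemble_features(co, "immune")
  expect_true(all(is.na(fbi$blocks$immune_tphe) |
                    fbi$blocks$immune_tphe >= 0))
})

test_that("missing site samples appear as whole-NA blocks, kept as rows", {
  co <- generate_cohort(sim_config(n_subjects = 25, seed = 8,
                                   site_missing_rate = 0.3))
  fb <- assemble_features(co, "microbiome")
  na_nasal <- rowSums(is.na(fb$blocks$nasal)) > 0
  expect_gt(sum(na_nasal), 0)
  # NA rows are all-NA (block granularity)
  expect_true(all(rowSums(is.na(fb$blocks$nasal)) %in%
                    c(0, ncol(fb$blocks$nasal))))
})

test_that("tuning and prediction are deterministic and leak-free", {
  co <- small_cohort(35, seed = 19)
  fb <- assemble_features(co, "microbiome")
  p1 <- tune_and_predict(fb, seed = 4, n_draws = 8)
  p2 <- tune_and_predict(fb, seed = 4, n_draws = 8)
  expect_identical(p1$alpha, p2$alpha)
  expect_identical(p1$lambda, p2$lambda)
  expect_identical(p1$predictions$yhat, p2$predictions$yhat)
  expect_true(all(is.finite(p1$predictions$yhat)))
  # every sample's fold excludes its subject
  folds <- tapply(p1$predictions$fold, p1$predictions$subject,
                  function(f) length(unique(f)))
  expect_true(all(folds == 1))
  # permuted target: grouped CV makes held-out R2 collapse
  fbp <- fb
  fbp$pma_days <- with_seed_perm(fb$pma_days, fb$subject, seed = 1)
  pp <- tune_and_predict(fbp, seed = 4, n_draws = 8)
  expect_lte(pp$r2, 0.05)
})

test_that("a noiseless linear target is recovered almost exactly", {
  set.seed(21)
  n <- 400
  sids <- sprintf("q%03d", rep(1:80, each = 5))
  X <- matrix(rnorm(n * 10), n)
  colnames(X) <- paste0("x", 1:10)
  y_weeks <- 2^(4 + X %*% c(0.2, -0.1, 0.15, rep(0, 7)))
  fb <- structure(list(
    blocks = list(main = X), subject = sids,
    pma_days = as.numeric(y_weeks) * 7,
    row_key = sprintf("r%03d", 1:n), system = "synthetic"),
    class = "codevel_features")
  p <- tune_and_predict(fb, seed = 2, n_draws = 30)
  expect_gte(p$r2, 0.95)
  expect_lt(abs(p$r2 - p$r2_log), 0.1)
})

test_that("trajectory BLUPs shrink but track an outlying subject", {
  set.seed(22)
  n_subj <- 60
  t <- seq(-0.3, 1.3, length.out = 12)
  preds <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    a <- if (i == 1) 0.5 else rnorm(1, 0, 0.05)
    b <- if (i == 1) 1.4 else rnorm(1, 1, 0.05)
    data.frame(subject = sprintf("s%02d", i),
               pma_days = 259 * 2^t,
               yhat = log2(37) + a + b * t + rnorm(12, 0, 0.05))
  }))
  tr <- fit_trajectories(preds)
  out <- tr[tr$subject == "s01", ]
  ols <- coef(lm(I(yhat - log2(37)) ~ I(log2(pma_days / 259)),
                 preds[preds$subject == "s01", ]))
  # shrunk towards the population but still clearly extreme and same-signed
  expect_gt(out$alpha, 0.3)
  expect_lt(out$alpha, ols[1] + 0.05)
  expect_gt(out$beta, 1.2)
  expect_gt(out$z_alpha, 2)
  # a subject at the medians scores z near 0
  mid <- which.min(abs(tr$alpha - median(tr$alpha)))
  expect_lt(abs(tr$z_alpha[mid]), 0.5)
})

test_that("developmental index joins systems and flags missing entries", {
  t1 <- data.frame(subject = c("a", "b", "c"), z_alpha = 1:3 / 2,
                   z_beta = -(1:3) / 2)
  t2 <- data.frame(subject = c("b", "c", "d"), z_alpha = 0:2 / 3,
                   z_beta = (0:2) / 3)
  di <- developmental_index(t1, t2)
  expect_named(di, c("subject", "micro_z_alpha", "micro_z_beta",
                     "immune_z_alpha", "immune_z_beta"))
  expect_equal(nrow(di), 4)
  expect_true(is.na(di$immune_z_alpha[di$subject == "a"]))
  expect_true(all(is.finite(unlist(di[di$subject == "b", -1]))))
  t3 <- data.frame(subject = "zz", z_alpha = 0, z_beta = 0)
  expect_error(developmental_index(t1, t3), "shared")
})

test_that("doubling trajectory spread increases DI feature variance", {
  vv <- vapply(c(0.08, 0.15, 0.30), function(s) {
    co <- generate_cohort(sim_config(n_subjects = 40, seed = 31,
                                     trajectory_sd = c(s, s)))
    fb <- assemble_features(co, "microbiome")
    tr <- fit_trajectories(tune_and_predict(fb, seed = 5, n_draws = 8))
    var(tr$alpha)
  }, numeric(1))
  expect_true(all(diff(vv) > 0))
})
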