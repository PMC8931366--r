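test_that("prevalence filter keeps exactly the sufficiently common features", {
  set.seed(1)
  # 10 features with prevalences 1%..10% across 100 samples
  X <- matrix(0L, 100, 10)
  for (j in 1:10) X[seq_len(j * 1), j] <- 1L  # j% prevalence
  X <- X[sample(100), ]
  kept <- filter_prevalence(X, 0.05)
  expect_equal(ncol(kept), 6)
  expect_identical(filter_prevalence(X, 0), X)
  # 4-of-100 feature is dropped at the 5% threshold
  expect_false(4 %in% colSums(kept > 0))
  expect_error(filter_prevalence(X, 0.5), "features present")
})

test_that("count normalization floors proportions times the depth constant", {
  expect_equal(as.numeric(normalize_counts(rbind(c(0.5, 0.3, 0.2)), 2250)),
               c(1125, 675, 450))
  out <- normalize_counts(rbind(rep(1 / 3, 3)), 100)
  expect_equal(as.numeric(out), c(33, 33, 33))
  expect_equal(sum(out), 99)
  imm <- rbind(c(0.123456, 0.876544))
  expect_equal(as.numeric(normalize_counts(imm, 50000)),
               as.numeric(floor(imm * 50000)))
  expect_error(normalize_counts(rbind(c(-0.1, 1.1)), 100), "negative")
})

test_that("DM log density matches the Polya-urn enumeration oracle", {
  expect_equal(dirmult_loglik(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_equal(dirmult_loglik(c(1, 0), c(1, 1)), log(1 / 2))
  set.seed(42)
  for (J in 2:3) {
    # every count vector with N <= 6, a fresh alpha each time
    grid <- expand.grid(rep(list(0:6), J))
    grid <- grid[rowSums(grid) <= 6 & rowSums(grid) > 0, ]
    for (r in seq_len(nrow(grid))) {
      x <- as.numeric(grid[r, ])
      alpha <- runif(J, 0.2, 5)
      expect_equal(dirmult_loglik(x, alpha), polya_urn_logprob(x, alpha),
                   tolerance = 1e-10)
    }
  }
  expect_error(dirmult_loglik(c(1, 1), c(1, -1)), "positive")
})

test_that("single-component fit matches a direct optimizer", {
  sim <- sim_dmm_counts(K = 1, J = 8, n = 200, precision = 20, seed = 3)
  f1 <- fit_dmm(sim$counts, 1, seed = 1, tol = 1e-10)
  # independent route: direct optimization of the unweighted DM likelihood
  nll <- function(la) -sum(vapply(seq_len(nrow(sim$counts)), function(i)
    dirmult_loglik(sim$counts[i, ], exp(la)), numeric(1)))
  direct <- optim(rep(0, 8), nll, method = "L-BFGS-B", lower = -15, upper = 9,
                  control = list(maxit = 500, factr = 10))
  expect_equal(f1$loglik, -direct$value, tolerance = 1e-6 * abs(direct$value))
})

test_that("parameter recovery for a single component at n = 500", {
  set.seed(8)
  J <- 10
  alpha_true <- runif(J, 0.5, 6)
  X <- t(vapply(1:500, function(i) {
    p <- rgamma(J, alpha_true)
    rmultinom(1, 1500, p / sum(p))[, 1]
  }, numeric(J)))
  f <- fit_dmm(X, 1, seed = 2, tol = 1e-9)
  rel_err <- abs(f$alpha[1, ] - alpha_true) / alpha_true
  expect_true(all(rel_err[alpha_true >= 0.5] < 0.15))
})

test_that("EM is deterministic under a fixed seed and loglik is monotone", {
  sim <- sim_dmm_counts(K = 3, J = 12, n = 300, seed = 5)
  f1 <- fit_dmm(sim$counts, 3, seed = 7)
  f2 <- fit_dmm(sim$counts, 3, seed = 7)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$alpha, f2$alpha)
  expect_true(all(diff(f1$loglik_trace) > -1e-8 * (abs(f1$loglik) + 1)))
})

test_that("model selection recovers K and enumeration orders by mean PMA", {
  sim <- sim_dmm_counts(K = 3, J = 20, n = 400, precision = 50, seed = 11)
  sel <- select_k(sim$counts, k_range = 1:5, seed = 2)
  expect_equal(sel$best_k, 3)
  expect_equal(nrow(sel$evidence), 5)
  # single-component data selects K = 1
  sim1 <- sim_dmm_counts(K = 1, J = 12, n = 250, precision = 30, seed = 12)
  sel1 <- select_k(sim1$counts, k_range = 1:3, seed = 3)
  expect_equal(sel1$best_k, 1)

  # enumeration: give component with larger mean PMA the later label
  pma <- 200 + 40 * sim$component + rnorm(400, 0, 5)
  asg <- assign_and_enumerate(sel$best_fit, sim$counts, pma)
  expect_equal(rowSums(asg$posterior), rep(1, 400), tolerance = 1e-8)
  expect_true(!is.unsorted(asg$mean_pma_per_state, na.rm = TRUE))
  expect_equal(asg$label, max.col(asg$posterior, ties.method = "first"))
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(asg$label, sim$component), 0.8)
})

test_that("K = 1 assignment is degenerate and relabeling is a bijection", {
  sim <- sim_dmm_counts(K = 1, J = 6, n = 50, seed = 4)
  f <- fit_dmm(sim$counts, 1, seed = 1)
  asg <- assign_and_enumerate(f, sim$counts, runif(50, 200, 400))
  expect_true(all(asg$label == 1))
  expect_equal(as.numeric(asg$posterior), rep(1, 50))
  f3 <- fit_dmm(sim_dmm_counts(K = 3, J = 10, n = 200, seed = 6)$counts, 3,
                seed = 2)
  asg3 <- assign_and_enumerate(f3, sim_dmm_counts(K = 3, J = 10, n = 200,
                                                  seed = 6)$counts,
                               runif(200, 150, 700))
  expect_setequal(asg3$label_map, 1:3)
})

test_that("mixture weights stay on the simplex and alphas positive", {
  sim <- sim_dmm_counts(K = 2, J = 8, n = 150, seed = 9)
  f <- fit_dmm(sim$counts, 2, seed = 5)
  expect_equal(sum(f$pi), 1, tolerance = 1e-12)
  expect_true(all(f$alpha > 0))
  expect_s3_class(f, "codevel_dmm")
  expect_output(print(f), "Dirichlet-multinomial mixture")
  expect_equal(dim(coef(f)), c(2, 8))
})
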