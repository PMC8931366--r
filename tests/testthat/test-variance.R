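test_that("ILR maps the uniform composition to zero and inverts exactly", {
  expect_equal(as.numeric(ilr_transform(matrix(1 / 3, 1, 3))), c(0, 0))
  set.seed(2)
  comp <- matrix(rgamma(40 * 7, 2), 40)
  comp <- comp / rowSums(comp)
  z <- ilr_transform(comp)
  expect_equal(ncol(z), 6)
  expect_lt(max(abs(ilr_inverse(z) - comp)), 1e-10)
  expect_error(ilr_transform(matrix(c(0, 1, 0, 1), 2)), "positive")
})

test_that("block preparation drops low-variance features and handles zeros", {
  set.seed(3)
  comp <- matrix(rgamma(60 * 5, 2), 60)
  comp <- comp / rowSums(comp)
  # a nearly-constant feature with variance below 1e-4
  flat <- 0.02 + rnorm(60, 0, 0.003)
  m <- cbind(comp * (1 - flat), flat)
  colnames(m) <- paste0("f", 1:6)
  expect_lt(var(m[, 6]), 1e-4)
  out <- prepare_block(m)
  expect_false("f6" %in% attr(out, "feature_ids"))
  expect_equal(ncol(out), 4)
  # zeros replaced by the multiplicative pseudocount, finite output
  mz <- comp
  mz[1, 1] <- 0
  mz <- mz / rowSums(mz)
  outz <- prepare_block(mz, var_threshold = 0)
  expect_true(all(is.finite(outz)))
  expect_gt(attr(outz, "pseudocount"), 0)
  expect_error(prepare_block(m, var_threshold = 0.5), "fewer than 2")
})

test_that("adjusted R2 is 1 for a saturating fit and ~0 under the null", {
  set.seed(4)
  n <- 500
  Y <- matrix(rnorm(n * 3), n)
  # response duplicated as predictor: residuals vanish
  sat <- manova_r2(Y, as.data.frame(Y))
  expect_equal(sat$r2_adj, 1, tolerance = 1e-10)
  nul <- manova_r2(Y, data.frame(x = rnorm(n)))
  expect_lt(abs(nul$r2_adj), 0.02)
  expect_true(nul$p_value > 0 && nul$p_value < 1)
})

test_that("Wilks test p-values are uniform under the null", {
  set.seed(5)
  p <- replicate(200, {
    Y <- matrix(rnorm(80 * 2), 80)
    manova_r2(Y, data.frame(x = rnorm(80)))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("R2 is invariant to response column order and basis sign flips", {
  set.seed(6)
  n <- 120
  comp <- matrix(rgamma(n * 5, 2), n)
  comp <- comp / rowSums(comp)
  x <- data.frame(x = rowSums(comp[, 1:2]) + rnorm(n, 0, 0.1))
  Y <- prepare_block(comp)
  r1 <- manova_r2(Y, x)$r2_adj
  r2 <- manova_r2(Y[, rev(seq_len(ncol(Y)))], x)$r2_adj
  r3 <- manova_r2(-Y, x)$r2_adj
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_equal(r1, r3, tolerance = 1e-10)
})

test_that("age adjustment attenuates a mediated cross-system association", {
  set.seed(7)
  n <- 400
  age <- runif(n, 0, 1)
  X <- matrix(rnorm(n * 4, sd = 0.3), n) + age           # age -> X
  Y <- matrix(rnorm(n * 3, sd = 0.3), n) + 2 * age       # age -> Y
  raw <- manova_r2(Y, as.data.frame(X))
  adj <- manova_r2(Y, cbind(data.frame(age = age), as.data.frame(X)),
                   data.frame(age = age))
  expect_gt(raw$r2_adj, 0.3)
  expect_lt(adj$r2_adj, raw$r2_adj / 2)
})

test_that("BIC follows the printed formula and prefers the true age driver", {
  set.seed(8)
  n <- 300
  pma <- runif(n, 150, 700)
  dol <- pma - runif(n, 160, 290)                        # decoupled offset
  Y <- matrix(rnorm(n * 3, sd = 0.3), n) + log2(pma / 259)
  b_pma <- manova_r2(Y, data.frame(a = log2(pma / 259)))$bic
  b_dol <- manova_r2(Y, data.frame(a = log2(pmax(dol, 1) / 259)))$bic
  expect_lt(b_pma, b_dol)
  # determinism
  expect_identical(b_pma, manova_r2(Y, data.frame(a = log2(pma / 259)))$bic)
  # p = 1 edge: univariate intercept-only model has penalty n*log(1) = 0
  y1 <- matrix(rnorm(50), 50)
  f <- codevel:::fit_mlm(y1, NULL)
  expect_equal(manova_bic(f), -2 * (-50 / 2 * (log(2 * pi) +
    log(sum(f$residuals^2) / 50) + 1)), tolerance = 1e-8)
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  set.seed(9)
  n <- 60
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 2), n)
  w <- testthat::capture_warnings(manova_r2(Y, data.frame(a = x, b = x)))
  expect_match(w, "aliased", all = FALSE)
  suppressWarnings(
    expect_error(manova_r2(Y[1:3, ], as.data.frame(matrix(rnorm(15), 3))),
                 "exceed"))
})
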