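# Shared fixture: per-subject sample counts with state-1 occupancy odds
# driven (or not) by gestational age at birth.
make_enrichment_fixture <- function(n = 150, ga_coef = 0, seed = 1) {
  set.seed(seed)
  sids <- sprintf("e%03d", seq_len(n))
  ga <- runif(n, 24, 41)
  n_samp <- sample(8:25, n, replace = TRUE)
  u <- rnorm(n, 0, 0.5)                      # subject random effect
  p1 <- plogis(-1 + ga_coef * (ga - 32) + u)
  k1 <- rbinom(n, n_samp, p1)
  labels <- integer(0)
  subj <- character(0)
  for (i in seq_len(n)) {
    labels <- c(labels, rep(1L, k1[i]), sample(2:3, n_samp[i] - k1[i],
                                               replace = TRUE))
    subj <- c(subj, rep(sids[i], n_samp[i]))
  }
  subjects <- data.frame(
    subject_id = sids, ga_birth = ga,
    delivery_mode = sample(c("vaginal", "cesarean"), n, TRUE),
    maternal_abx = runif(n) > 0.6, milk_months_gt50pct = rpois(n, 4),
    milk_any = runif(n) > 0.15, abx_inpatient_days = rpois(n, 6),
    abx_outpatient_courses = rpois(n, 1))
  list(labels = labels, subj = subj, subjects = subjects)
}

test_that("GA-independent occupancy yields CIs covering zero", {
  hits <- vapply(1:25, function(r) {
    fx <- make_enrichment_fixture(n = 80, ga_coef = 0, seed = 100 + r)
    rec <- enrichment_by_term(fx$labels, fx$subj, fx$subjects)
    r1 <- rec[rec$state == 1, ]
    r1$ci_low <= 0 && r1$ci_high >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a strong negative GA effect is recovered at n = 150", {
  fx <- make_enrichment_fixture(n = 150, ga_coef = -0.3, seed = 7)
  rec <- enrichment_by_term(fx$labels, fx$subj, fx$subjects)
  r1 <- rec[rec$state == 1, ]
  expect_lt(r1$effect, 0)
  expect_lt(r1$p_value, 0.05)
  expect_true(all(rec$q_value >= rec$p_value, na.rm = TRUE))
})

test_that("states without usable variation are skipped with a reason", {
  fx <- make_enrichment_fixture(n = 40, seed = 3)
  labels <- rep(2L, length(fx$labels))   # nobody ever in state 1
  labels[1] <- 1L
  rec <- enrichment_by_term(labels, fx$subj, fx$subjects)
  expect_true(any(!is.na(rec$reason)))
  expect_true(is.na(rec$effect[rec$state == 1]))
})

test_that("effects are equivariant under recoding of binary covariates", {
  fx <- make_enrichment_fixture(n = 100, ga_coef = -0.2, seed = 9)
  rec1 <- enrichment_by_term(fx$labels, fx$subj, fx$subjects)
  flipped <- fx$subjects
  flipped$maternal_abx <- !flipped$maternal_abx
  rec2 <- enrichment_by_term(fx$labels, fx$subj, flipped)
  expect_equal(rec1$effect, rec2$effect, tolerance = 1e-4)
})

test_that("null exposures are flagged at no more than the FDR level", {
  rate <- vapply(1:50, function(r) {
    set.seed(300 + r)
    n <- 200
    ever <- runif(n) < 0.35
    expos <- data.frame(e1 = runif(n) > 0.5, e2 = runif(n) > 0.7,
                        e3 = runif(n) > 0.5, e4 = runif(n) > 0.8)
    res <- exposure_model(ever, expos, ga = runif(n, 24, 41))
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(rate), 0.12)
})

test_that("an 8-fold odds exposure is detected at 10% FDR", {
  hits <- vapply(1:15, function(r) {
    set.seed(400 + r)
    n <- 150
    e1 <- runif(n) > 0.75
    ever <- runif(n) < plogis(-1.2 + log(8) * e1)
    expos <- data.frame(e1 = e1, e2 = runif(n) > 0.5, e3 = runif(n) > 0.5,
                        e4 = runif(n) > 0.8)
    res <- exposure_model(ever, expos, ga = runif(n, 24, 41))
    res$significant[res$exposure == "e1"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate and separated exposure designs are handled", {
  n <- 80
  expect_error(exposure_model(rep(1, n), data.frame(e = runif(n) > 0.5),
                              ga = runif(n, 24, 41)), "variation")
  # complete separation triggers the penalized fit
  set.seed(5)
  e <- rep(c(TRUE, FALSE), each = n / 2)
  res <- exposure_model(as.numeric(e), data.frame(e1 = e),
                        ga = runif(n, 24, 41))
  expect_equal(unique(res$model), "firth")
  expect_true(all(is.finite(res$effect)))
})

test_that("the penalized logistic fallback matches glm away from separation", {
  set.seed(11)
  n <- 400
  x <- cbind(1, rnorm(n), runif(n) > 0.5)
  y <- rbinom(n, 1, plogis(x %*% c(-0.5, 1, 0.7)))
  fir <- codevel:::firth_logistic(x, y)
  g <- glm(y ~ x - 1, family = binomial())
  expect_equal(unname(fir$coef), unname(coef(g)), tolerance = 0.1)
})
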