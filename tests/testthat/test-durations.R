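test_that("worked example: interval arithmetic over state change points", {
  d <- build_durations(data.frame(subject_id = "s1", dol = c(2, 10, 20, 40),
                                  state = c("A", "A", "B", "B")))
  expect_equal(d$days["s1", "A"], 15)
  expect_equal(d$days["s1", "B"], 35)
  expect_equal(unname(d$span["s1"]), 50)
})

test_that("a first sample after day 14 forfeits the initial interval", {
  d <- build_durations(data.frame(subject_id = "s1", dol = c(20, 30),
                                  state = c("A", "B")))
  expect_equal(d$days["s1", "A"], 0)
  expect_equal(d$days["s1", "B"], 10)
  # at the boundary the interval is kept
  d14 <- build_durations(data.frame(subject_id = "s1", dol = c(14, 30),
                                    state = c("A", "B")))
  expect_equal(d14$days["s1", "A"], 22)
})

test_that("uniform state occupies the whole observed span", {
  set.seed(1)
  dol <- sort(sample(0:300, 12))
  d <- build_durations(data.frame(subject_id = "s", dol = dol, state = "A"))
  expect_equal(unname(d$days["s", "A"]), unname(d$span["s"]))
})

test_that("durations equal the day-by-day nearest-sample oracle", {
  set.seed(99)
  for (rep in seq_len(1000)) {
    n <- sample(2:12, 1)
    dol <- sort(sample(0:400, n))
    state <- sample(LETTERS[1:4], n, replace = TRUE)
    d <- build_durations(data.frame(subject_id = "s", dol = dol,
                                    state = state))
    oracle <- daily_duration_oracle(dol, state)
    got <- d$days["s", names(oracle)]
    expect_equal(unname(got), unname(oracle))
    expect_equal(unname(sum(d$days["s", ])), unname(d$span["s"]))
  }
})

test_that("degenerate inputs: singletons excluded, duplicates deduplicated", {
  d <- build_durations(data.frame(subject_id = c("a", "b", "b", "b"),
                                  dol = c(5, 5, 15, 25),
                                  state = c("A", "A", "B", "B")))
  expect_false(d$included["a"])
  expect_match(d$reason["a"], "fewer than two")
  expect_warning(
    build_durations(data.frame(subject_id = "c", dol = c(5, 5, 20),
                               state = c("A", "B", "B"))),
    "duplicate")
  # unsorted input is sorted internally
  d2 <- build_durations(data.frame(subject_id = "s", dol = c(40, 2, 20, 10),
                                   state = c("B", "A", "B", "A")))
  expect_equal(d2$days["s", "A"], 15)
})

test_that("inclusion rules flag sparse inpatient and outpatient sampling", {
  mk <- function(dols) data.frame(subject_id = "s", dol = dols, state = "A")
  post6 <- c(70, 100, 130, 160, 190, 220)
  # 1 sample in 60 NICU days -> excluded
  d <- apply_inclusion(build_durations(mk(c(10, post6))), mk(c(10, post6)),
                       c(s = 60))
  expect_false(d$included["s"])
  expect_match(d$reason["s"], "NICU")
  # 5 post-discharge samples -> excluded
  d2 <- apply_inclusion(build_durations(mk(c(5, 15, 25, post6[1:5]))),
                        mk(c(5, 15, 25, post6[1:5])), c(s = 30))
  expect_false(d2$included["s"])
  expect_match(d2$reason["s"], "post discharge")
  # boundary: 2 samples in 30 NICU days and 6 post-discharge -> included
  d3 <- apply_inclusion(build_durations(mk(c(5, 25, post6))),
                        mk(c(5, 25, post6)), c(s = 30))
  expect_true(d3$included["s"])
})

test_that("scan recovers an injected duration effect with small bias", {
  logrr <- replicate(10, {
    fx <- make_scan_fixture(n = 120, effect = log(1.5),
                            seed = sample.int(1e6, 1))
    res <- association_scan(fx$dur, list(birth = fx$voi), fx$conf)
    res$log_rate_ratio[res$state == "st1" & res$voi == "v1"]
  })
  expect_true(all(is.finite(logrr)))
  expect_gt(mean(sign(logrr)), 0.8)               # sign recovered
  expect_lt(abs(mean(logrr) - log(1.5)), 0.1)     # |bias| of log-RR < 0.1
})

test_that("scan filters sparse VOIs and rare states before testing", {
  fx <- make_scan_fixture(n = 60, seed = 3)
  voi <- fx$voi
  voi[10:60, 2] <- NA                              # 9 observations only
  fx$dur$days[, 4] <- 0
  fx$dur$days[1:3, 4] <- 5                         # present in 5% < 10%
  res <- association_scan(fx$dur, list(birth = voi), fx$conf)
  expect_false("v2" %in% res$voi)
  expect_false("st4" %in% res$state)
})

test_that("scan output is invariant to VOI column order and BH is monotone", {
  fx <- make_scan_fixture(n = 80, seed = 4)
  r1 <- association_scan(fx$dur, list(birth = fx$voi), fx$conf)
  r2 <- association_scan(fx$dur, list(birth = fx$voi[, c(3, 1, 2)]), fx$conf)
  key <- function(d) d[order(d$state, d$voi), c("log_rate_ratio", "p_value")]
  expect_equal(key(r1), key(r2), ignore_attr = TRUE)
  ok <- is.finite(r1$p_value)
  o <- order(r1$p_value[ok])
  expect_true(!is.unsorted(r1$q_value[ok][o]))
  expect_true(all(r1$q_value[ok] >= r1$p_value[ok]))
})
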