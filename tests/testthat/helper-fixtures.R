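# Synthetic duration-table fixture for the quasi-Poisson scan tests:
# per-subject days in n_states states, optionally coupling state 1 to the
# first variable of interest with a given log rate ratio per VOI SD.
make_scan_fixture <- function(n = 120, effect = 0, seed = 1, n_states = 4,
                              n_vois = 3) {
  set.seed(seed)
  sids <- sprintf("p%03d", seq_len(n))
  span <- runif(n, 200, 420)
  voi <- matrix(rnorm(n * n_vois), n,
                dimnames = list(sids, paste0("v", seq_len(n_vois))))
  base <- span / n_states
  days <- matrix(0, n, n_states, dimnames = list(sids, paste0("st", 1:n_states)))
  for (k in seq_len(n_states)) {
    # the focal state is a minor share of the span, so the log-span
    # sampling-intensity covariate stays essentially design-driven
    rate <- base * (if (k == 1) exp(effect * voi[, 1]) / 4 else 1)
    days[, k] <- rgamma(n, shape = 4, rate = 4 / rate)
  }
  span <- rowSums(days) # observed span is whatever the states sum to
  dur <- structure(list(
    days = days, span = setNames(span, sids),
    log_span = setNames(log(span), sids),
    n_samples = setNames(rep(10L, n), sids),
    included = setNames(rep(TRUE, n), sids),
    reason = setNames(rep(NA_character_, n), sids)), class = "codevel_durations")
  conf <- data.frame(
    subject_id = sids, delivery_mode = sample(c("vaginal", "cesarean"), n, TRUE),
    ga_birth = runif(n, 24, 41), milk_any = runif(n) > 0.2,
    milk_months_gt50pct = rpois(n, 4), abx_inpatient_days = rpois(n, 6),
    abx_outpatient_courses = rpois(n, 1))
  list(dur = dur, voi = voi, conf = conf)
}
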