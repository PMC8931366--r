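# Midpoint-interval allocation for one subject's ordered samples.
# Sample j owns [mid(j-1,j), mid(j,j+1)); the first interval starts at day 0
# only when the first sample falls within `first_day_rule` days of birth
# (otherwise it starts at mid(1,2), i.e. the first sample contributes no
# time); the subject is assumed to remain in the final observed state for
# half the final inter-sample gap.
midpoint_intervals <- function(dol, state, first_day_rule = 14) {
  n <- length(dol)
  stopifnot(n >= 2, !is.unsorted(dol))
  mids <- (dol[-n] + dol[-1]) / 2
  start <- c(if (dol[1] <= first_day_rule) 0 else mids[1], mids)
  end <- c(mids, dol[n] + (dol[n] - dol[n - 1]) / 2)
  data.frame(state = state, days = end - start)
}

#' Days spent in each state type per subject
#'
#' Converts longitudinal state assignments into a subject-by-state table of
#' days, summing interval lengths between state change points. Intervals run
#' from midpoint to midpoint of the sampled days of life; subjects enter
#' their first observed state at birth only if first sampled within 14 days
#' of life, and remain in their final observed state for half the final
#' inter-sample gap. Subjects with a single sample are excluded with a
#' recorded reason; duplicate (subject, day) records keep the first
#' occurrence with a warning; unsorted input is sorted internally.
#'
#' @param samples data.frame with columns `subject_id`, `dol`, `state`.
#' @return `codevel_durations`: list with `days` (subject x state matrix),
#'   `span` (days observed per subject; equals `rowSums(days)`), `log_span`
#'   (the sampling-intensity covariate), `n_samples`, `included`, `reason`.
#' @export
build_durations <- function(samples) {
  req <- c("subject_id", "dol", "state")
  if (!all(req %in% names(samples))) {
    stopf("samples must have columns %s", paste(req, collapse = ", "))
  }
  states <- sort(unique(as.character(samples$state)))
  sids <- unique(samples$subject_id)
  days <- matrix(0, length(sids), length(states),
                 dimnames = list(sids, states))
  span <- setNames(numeric(length(sids)), sids)
  n_samp <- setNames(integer(length(sids)), sids)
  included <- setNames(rep(TRUE, length(sids)), sids)
  reason <- setNames(rep(NA_character_, length(sids)), sids)
  for (sid in sids) {
    s <- samples[samples$subject_id == sid, ]
    s <- s[order(s$dol), ]
    if (anyDuplicated(s$dol)) {
      warnf("subject %s: duplicate sampling days; keeping first record", sid)
      s <- s[!duplicated(s$dol), ]
    }
    n_samp[sid] <- nrow(s)
    if (nrow(s) < 2) {
      included[sid] <- FALSE
      reason[sid] <- "fewer than two samples"
      next
    }
    iv <- midpoint_intervals(s$dol, as.character(s$state))
    agg <- tapply(iv$days, iv$state, sum)
    days[sid, names(agg)] <- agg
    span[sid] <- sum(iv$days)
  }
  structure(list(days = days, span = span, log_span = log(pmax(span, 1)),
                 n_samples = n_samp, included = included, reason = reason),
            class = "codevel_durations")
}

#' @export
print.codevel_durations <- function(x, ...) {
  cat(sprintf("Durations: %d subjects x %d states; %d included\n",
              nrow(x$days), ncol(x$days), sum(x$included)))
  invisible(x)
}

#' Sampling-density inclusion rules for the duration table
#'
#' Flags subjects sampled too sparsely for the days-in-state response to be
#' trustworthy: fewer than one sample per 30 inpatient (NICU) days, or fewer
#' than six samples after discharge. Reasons are machine-readable; the
#' filter is pure (no rows are removed).
#'
#' @param durations a `codevel_durations` object.
#' @param samples the sample data.frame the durations were built from
#'   (columns `subject_id`, `dol`).
#' @param discharge_dol named numeric vector of discharge day-of-life per
#'   subject (names = subject ids).
#' @return The updated `codevel_durations` with `included`/`reason` set.
#' @export
apply_inclusion <- function(durations, samples, discharge_dol) {
  stopifnot(inherits(durations, "codevel_durations"))
  for (sid in rownames(durations$days)) {
    if (!durations$included[sid]) next
    if (!sid %in% names(discharge_dol)) {
      durations$included[sid] <- FALSE
      durations$reason[sid] <- "no discharge day"
      next
    }
    dd <- discharge_dol[[sid]]
    s <- samples[samples$subject_id == sid, ]
    n_nicu <- sum(s$dol <= dd)
    n_post <- sum(s$dol > dd)
    if (dd > 0 && n_nicu / dd < 1 / 30) {
      durations$included[sid] <- FALSE
      durations$reason[sid] <- "fewer than one sample per 30 NICU-days"
    } else if (n_post < 6) {
      durations$included[sid] <- FALSE
      durations$reason[sid] <- "fewer than six samples post discharge"
    }
  }
  durations
}

#' Quasi-Poisson scan of state durations against immune variables
#'
#' For every (state, immune variable, timepoint) triple, regresses the days
#' a subject spent in the state on the variable of interest plus confounders
#' and the log observation span (sampling intensity), using quasi-Poisson
#' regression on floored day counts. The variable's significance is a
#' chi-square test on the change in deviance (scaled by the Pearson
#' dispersion) when it is dropped. Variables observed in fewer than ten
#' subjects are filtered before the scan, as are states occupied by fewer
#' than 10% of the remaining subjects. Numeric covariates are z-scored
#' except gestational age, coded as (GA - 37) weeks. Benjamini-Hochberg
#' correction is applied across the whole scan by default (10% FDR).
#'
#' @param durations an included-filtered `codevel_durations`.
#' @param vois named list over timepoints (`birth`, `discharge`,
#'   `one_year`) of subject x variable matrices of immune relative
#'   abundances (rownames = subject ids).
#' @param confounders data.frame of per-subject confounders with a
#'   `subject_id` column; the adjusted preset expects `delivery_mode`,
#'   `ga_birth`, `milk_any`, `milk_months_gt50pct`, `abx_inpatient_days`,
#'   `abx_outpatient_courses`. The baseline preset uses only premature
#'   birth (`ga_birth` < 37).
#' @param preset `"adjusted"` (full confounder set) or `"baseline"`.
#' @param fdr_scope `"global"` BH across all records (default) or
#'   `"per_timepoint"`.
#' @param fdr_level flagging threshold (default 0.10).
#' @param min_voi_obs,min_state_prop the pre-scan filters.
#' @return data.frame of association records: `state`, `voi`, `timepoint`,
#'   `log_rate_ratio` (per VOI standard deviation), `se`, `ci_low`,
#'   `ci_high`, `p_value`, `q_value`, `significant`, `reason`.
#' @export
association_scan <- function(durations, vois, confounders,
                             preset = c("adjusted", "baseline"),
                             fdr_scope = c("global", "per_timepoint"),
                             fdr_level = 0.10,
                             min_voi_obs = 10L, min_state_prop = 0.10) {
  stopifnot(inherits(durations, "codevel_durations"))
  preset <- match.arg(preset)
  fdr_scope <- match.arg(fdr_scope)
  keep <- rownames(durations$days)[durations$included]
  if (length(keep) < 3) stopf("fewer than 3 included subjects")
  days <- durations$days[keep, , drop = FALSE]
  log_span <- durations$log_span[keep]

  rownames(confounders) <- confounders$subject_id
  conf <- confounders[keep, , drop = FALSE]
  X_conf <- if (preset == "adjusted") {
    data.frame(
      cesarean = as.numeric(conf$delivery_mode == "cesarean"),
      ga_centered = conf$ga_birth - 37,
      milk_any = as.numeric(conf$milk_any),
      milk_months = as.numeric(scale(conf$milk_months_gt50pct)),
      abx_in = as.numeric(scale(conf$abx_inpatient_days)),
      abx_out = as.numeric(scale(conf$abx_outpatient_courses)),
      log_span = as.numeric(scale(log_span)),
      row.names = keep)
  } else {
    data.frame(preterm = as.numeric(conf$ga_birth < 37),
               log_span = as.numeric(scale(log_span)), row.names = keep)
  }
  # zero-variance covariates (e.g. all-preterm subcohorts) would alias
  for (j in names(X_conf)) {
    if (sd(X_conf[[j]], na.rm = TRUE) < 1e-10) X_conf[[j]] <- NULL
  }

  states <- colnames(days)
  state_prop <- colMeans(days > 0)
  states <- states[state_prop >= min_state_prop]

  recs <- list()
  for (tp in names(vois)) {
    V <- as.matrix(vois[[tp]])
    common <- intersect(rownames(V), keep)
    for (v in colnames(V)) {
      vv <- V[common, v]
      ok <- common[!is.na(vv)]
      if (length(ok) < min_voi_obs) next # VOI filtered pre-scan
      for (st in states) {
        rec <- scan_one(floor(days[ok, st]), vv[ok], X_conf[ok, , drop = FALSE])
        recs[[length(recs) + 1]] <- cbind(
          data.frame(state = st, voi = v, timepoint = tp,
                     stringsAsFactors = FALSE), rec)
      }
    }
  }
  if (length(recs) == 0) stopf("scan is empty after filtering")
  out <- do.call(rbind, recs)
  out$q_value <- NA_real_
  fam <- is.finite(out$p_value)
  if (fdr_scope == "global") {
    out$q_value[fam] <- p.adjust(out$p_value[fam], "BH")
  } else {
    for (tp in unique(out$timepoint)) {
      idx <- fam & out$timepoint == tp
      out$q_value[idx] <- p.adjust(out$p_value[idx], "BH")
    }
  }
  out$significant <- !is.na(out$q_value) & out$q_value <= fdr_level
  rownames(out) <- NULL
  out
}

scan_one <- function(y, voi, X_conf) {
  fail <- function(reason) data.frame(
    log_rate_ratio = NaN, se = NaN, ci_low = NaN, ci_high = NaN,
    p_value = NA_real_, reason = reason, stringsAsFactors = FALSE)
  if (sd(voi) < 1e-12) return(fail("zero-variance VOI in complete cases"))
  dat <- cbind(data.frame(.y = y, .voi = as.numeric(scale(voi))), X_conf)
  full <- tryCatch(
    suppressWarnings(glm(.y ~ ., data = dat, family = quasipoisson())),
    error = function(e) NULL)
  red <- tryCatch(
    suppressWarnings(glm(.y ~ . - .voi, data = dat, family = quasipoisson())),
    error = function(e) NULL)
  if (is.null(full) || is.null(red) || !full$converged) {
    return(fail("quasi-Poisson fit failed"))
  }
  disp <- max(sum(residuals(full, "pearson")^2) / full$df.residual, 1e-8)
  stat <- (red$deviance - full$deviance) / disp
  p <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  est <- coef(full)[".voi"]
  se <- sqrt(diag(vcov(full))[".voi"]) # vcov already dispersion-scaled
  data.frame(log_rate_ratio = unname(est), se = unname(se),
             ci_low = unname(est - 1.96 * se), ci_high = unname(est + 1.96 * se),
             p_value = p, reason = NA_character_, stringsAsFactors = FALSE)
}
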