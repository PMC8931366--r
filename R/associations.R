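#' State-type enrichment by gestational age at birth
#'
#' For each state type, models each subject's (samples in state, samples not
#' in state) counts against gestational age at birth plus confounders with a
#' logistic mixed model carrying a random subject intercept:
#' `cbind(in, out) ~ ga_birth + confounders + (1 | subject)`. The default
#' confounder set is mode of delivery, maternal antibiotic use during
#' pregnancy, months of >50% breastmilk feeding, any breastmilk before
#' discharge, inpatient antibiotic days, and outpatient antibiotic courses.
#' On non-convergence the model falls back to a fixed-effects logistic fit
#' with subject-clustered sandwich-free binomial errors, flagged in the
#' output. States with no assigned samples are skipped with a reason.
#'
#' @param labels integer/character state label per sample.
#' @param sample_subjects subject id per sample (aligned with `labels`).
#' @param subjects data.frame with `subject_id`, `ga_birth` and the
#'   confounder columns (`delivery_mode`, `maternal_abx`,
#'   `milk_months_gt50pct`, `milk_any`, `abx_inpatient_days`,
#'   `abx_outpatient_courses`).
#' @param confounders character vector naming the confounder columns; set
#'   `character(0)` to adjust for nothing.
#' @return data.frame of enrichment records: one row per state with the GA
#'   log-odds `effect`, `ci_low`, `ci_high`, `p_value`, BH `q_value`,
#'   `model` descriptor and `reason` for skipped states.
#' @export
enrichment_by_term <- function(labels, sample_subjects, subjects,
                               confounders = c(
                                 "delivery_mode", "maternal_abx",
                                 "milk_months_gt50pct", "milk_any",
                                 "abx_inpatient_days",
                                 "abx_outpatient_courses")) {
  stopifnot(length(labels) == length(sample_subjects))
  rownames(subjects) <- subjects$subject_id
  tot <- table(sample_subjects)
  sids <- names(tot)
  states <- sort(unique(labels))
  recs <- list()
  for (st in states) {
    k <- table(factor(sample_subjects[labels == st], levels = sids))
    n <- as.integer(tot)
    k <- as.integer(k)
    if (sum(k) == 0) {
      recs[[as.character(st)]] <- data.frame(
        state = st, effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, model = NA_character_,
        reason = "no samples in state", stringsAsFactors = FALSE)
      next
    }
    # need subjects observed both in and out of the state
    if (sum(k > 0) < 2 || sum(k < n) < 2) {
      recs[[as.character(st)]] <- data.frame(
        state = st, effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, model = NA_character_,
        reason = "insufficient between-subject variation",
        stringsAsFactors = FALSE)
      next
    }
    dat <- data.frame(k = k, n = n, subject = sids,
                      ga = subjects[sids, "ga_birth"])
    for (cf in confounders) dat[[cf]] <- coerce_covariate(subjects[sids, cf])
    rhs <- paste(c("ga", confounders), collapse = " + ")
    fml <- as.formula(paste("cbind(k, n - k) ~", rhs, "+ (1 | subject)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(fml, data = dat, family = binomial()))),
      error = function(e) NULL)
    rec <- NULL
    if (!is.null(fit) && is.finite(logLik(fit))) {
      cc <- tryCatch({
        sm <- summary(fit)$coefficients
        sm["ga", , drop = FALSE]
      }, error = function(e) NULL)
      if (!is.null(cc)) {
        est <- cc[1, "Estimate"]; se <- cc[1, "Std. Error"]
        rec <- data.frame(
          state = st, effect = est, ci_low = est - 1.96 * se,
          ci_high = est + 1.96 * se, p_value = cc[1, "Pr(>|z|)"],
          model = "glmm", reason = NA_character_, stringsAsFactors = FALSE)
      }
    }
    if (is.null(rec)) {
      # fixed-effects fallback (quasibinomial absorbs the overdispersion the
      # random intercept would have carried)
      fml2 <- as.formula(paste("cbind(k, n - k) ~", rhs))
      f2 <- suppressWarnings(glm(fml2, data = dat,
                                 family = stats::quasibinomial()))
      sm <- summary(f2)$coefficients
      est <- sm["ga", 1]; se <- sm["ga", 2]
      rec <- data.frame(
        state = st, effect = est, ci_low = est - 1.96 * se,
        ci_high = est + 1.96 * se,
        p_value = 2 * pnorm(-abs(est / se)),
        model = "quasibinomial_fallback", reason = NA_character_,
        stringsAsFactors = FALSE)
    }
    recs[[as.character(st)]] <- rec
  }
  out <- do.call(rbind, recs)
  out$q_value <- NA_real_
  fam <- is.finite(out$p_value)
  out$q_value[fam] <- p.adjust(out$p_value[fam], "BH")
  rownames(out) <- NULL
  out
}

coerce_covariate <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.character(x)) return(factor(x))
  x
}

#' Exposure model for ever entering a state type
#'
#' Logistic regression of a per-subject ever-in-state flag on a joint block
#' of exposures of interest (e.g. maternal antibiotic use, clinical
#' chorioamnionitis, membrane rupture > 18 h, CMV positivity) with a smooth
#' gestational-age term (natural cubic spline, 3 df) and confounders (mode
#' of delivery, race, sex). Exposure p-values are Benjamini-Hochberg
#' corrected within the exposure family and flagged at 10% FDR. Complete
#' separation triggers a Firth-type penalized refit, flagged in the output.
#'
#' @param ever logical/0-1 vector, one per subject.
#' @param exposures data.frame of the exposure block (one row per subject).
#' @param ga gestational age at birth (weeks), one per subject.
#' @param confounders data.frame of confounders (or `NULL`).
#' @param ga_df spline degrees of freedom for the GA smooth (default 3).
#' @param fdr_level flagging threshold (default 0.10).
#' @return data.frame of records, one per exposure: `effect` (log-odds),
#'   `ci_low`, `ci_high`, `p_value`, `q_value`, `significant`, `model`.
#' @export
exposure_model <- function(ever, exposures, ga, confounders = NULL,
                           ga_df = 3, fdr_level = 0.10) {
  ever <- as.numeric(ever)
  if (length(unique(ever)) < 2) {
    stopf("ever-in-state flag has no variation")
  }
  exposures <- as.data.frame(exposures)
  dat <- data.frame(.y = ever)
  for (v in names(exposures)) dat[[v]] <- coerce_covariate(exposures[[v]])
  dat$.ga <- ga
  if (!is.null(confounders)) {
    confounders <- as.data.frame(confounders)
    for (v in names(confounders)) dat[[v]] <- coerce_covariate(confounders[[v]])
  }
  rhs <- paste(c(names(exposures),
                 sprintf("splines::ns(.ga, df = %d)", ga_df),
                 setdiff(names(dat), c(".y", ".ga", names(exposures)))),
               collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
  model <- "logistic"
  if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE) ||
      any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)) {
    X <- model.matrix(fml, dat)
    fit <- firth_logistic(X, dat$.y)
    model <- "firth"
  }
  if (model == "logistic") {
    sm <- summary(fit)$coefficients
  } else {
    sm <- cbind(fit$coef, fit$se, fit$coef / fit$se,
                2 * pnorm(-abs(fit$coef / fit$se)))
    rownames(sm) <- names(fit$coef)
  }
  recs <- lapply(names(exposures), function(v) {
    rows <- grep(paste0("^", v), rownames(sm))
    if (length(rows) == 0) {
      return(data.frame(exposure = v, effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        model = model, stringsAsFactors = FALSE))
    }
    est <- sm[rows[1], 1]; se <- sm[rows[1], 2]
    data.frame(exposure = v, effect = est, ci_low = est - 1.96 * se,
               ci_high = est + 1.96 * se, p_value = sm[rows[1], 4],
               model = model, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$q_value <- p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$q_value) & out$q_value <= fdr_level
  rownames(out) <- NULL
  out
}

# Firth-type (Jeffreys-prior penalized) logistic regression by Newton
# iteration on the modified score U*(b) = X'(y - p + h (1/2 - p)); finite
# estimates exist under complete separation.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    inv <- tryCatch(solve(XtWX), error = function(e)
      solve(XtWX + diag(1e-8, ncol(X))))
    h <- rowSums((X %*% inv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- inv %*% U
    b_new <- b + drop(step)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  eta <- drop(X %*% b)
  w <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-10)
  V <- tryCatch(solve(crossprod(X, X * w)), error = function(e)
    solve(crossprod(X, X * w) + diag(1e-8, ncol(X))))
  list(coef = setNames(drop(b), colnames(X)),
       se = setNames(sqrt(diag(V)), colnames(X)), iter = it)
}
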