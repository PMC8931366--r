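#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of [generate_cohort()]. Defaults
#' emulate a mixed preterm/full-term birth cohort followed through the first
#' year: weekly inpatient and monthly outpatient mucosal sampling at two body
#' sites, T cell composition at birth/discharge/one-year, latent
#' maturation-ordered state types generating Dirichlet-multinomial counts,
#' per-subject maturation intercept/slope heterogeneity, and a binary
#' respiratory outcome coupled to the trajectory parameters.
#'
#' @param n_subjects number of subjects.
#' @param preterm_fraction expected fraction born before 37 weeks.
#' @param ga_range_weeks (min, max) gestational age at birth, weeks.
#' @param n_taxa_nasal,n_taxa_rectal taxa per microbiota site.
#' @param n_immune_pops T cell populations per assay (Tphe, ICS).
#' @param k_states latent state types per system.
#' @param state_concentration Dirichlet precision of each state's
#'   composition; larger = tighter, better-separated states.
#' @param depth_range (min, max) reads per microbiota sample.
#' @param inpatient_interval_days,outpatient_interval_days,followup_days
#'   sampling scheme: weekly while hospitalized, monthly after discharge,
#'   through `followup_days` days of life.
#' @param trajectory_sd (intercept_sd, slope_sd) of the per-subject
#'   maturation deviations `alpha_i ~ N(0, sd)` and `beta_i ~ N(1, sd)`.
#' @param ordinal_scale logistic noise scale of the cumulative-logit state
#'   coupling; smaller = states track maturation more tightly.
#' @param maturation_headroom multiplier extending the state-type axis past
#'   the followup horizon (default 1.6), so maturation continues beyond the
#'   observation window instead of saturating in the final state.
#' @param site_missing_rate probability a scheduled microbiota site sample
#'   is missing (exercises block missingness downstream).
#' @param immune_missing_rate probability a blood timepoint is missing.
#' @param prd_coefs logistic coefficients of the outcome on the 4 true
#'   developmental-index features (micro intercept z, micro slope z,
#'   immune intercept z, immune slope z).
#' @param prd_intercept logistic intercept controlling outcome prevalence.
#' @param seed master integer seed; per-subject substreams are hashed from
#'   it so adding subjects never perturbs existing ones.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 150L,
                       preterm_fraction = 0.55,
                       ga_range_weeks = c(23, 41.6),
                       n_taxa_nasal = 30L,
                       n_taxa_rectal = 30L,
                       n_immune_pops = 20L,
                       k_states = 12L,
                       state_concentration = 100,
                       depth_range = c(1000L, 3000L),
                       inpatient_interval_days = 7L,
                       outpatient_interval_days = 30L,
                       followup_days = 450L,
                       trajectory_sd = c(0.15, 0.15),
                       ordinal_scale = 0.08,
                       maturation_headroom = 1.5,
                       site_missing_rate = 0.05,
                       immune_missing_rate = 0.15,
                       prd_coefs = c(0.5, 0.5, 0.5, 0.5),
                       prd_intercept = -1,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), preterm_fraction = preterm_fraction,
    ga_range_weeks = as.numeric(ga_range_weeks),
    n_taxa_nasal = as.integer(n_taxa_nasal),
    n_taxa_rectal = as.integer(n_taxa_rectal),
    n_immune_pops = as.integer(n_immune_pops),
    k_states = as.integer(k_states),
    state_concentration = as.numeric(state_concentration),
    depth_range = as.integer(depth_range),
    inpatient_interval_days = as.integer(inpatient_interval_days),
    outpatient_interval_days = as.integer(outpatient_interval_days),
    followup_days = as.integer(followup_days),
    trajectory_sd = as.numeric(trajectory_sd),
    ordinal_scale = as.numeric(ordinal_scale),
    maturation_headroom = as.numeric(maturation_headroom),
    site_missing_rate = site_missing_rate,
    immune_missing_rate = immune_missing_rate,
    prd_coefs = as.numeric(prd_coefs),
    prd_intercept = as.numeric(prd_intercept),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_subjects < 1) stopf("n_subjects must be >= 1")
    if (preterm_fraction < 0 || preterm_fraction > 1) {
      stopf("preterm_fraction must be in [0, 1]")
    }
    if (length(ga_range_weeks) != 2 || diff(ga_range_weeks) <= 0) {
      stopf("ga_range_weeks must be (min, max) with min < max")
    }
    if (ga_range_weeks[1] >= 37 && preterm_fraction > 0) {
      stopf("preterm subjects requested but ga range is all-term")
    }
    if (min(n_taxa_nasal, n_taxa_rectal, n_immune_pops) < 1) {
      stopf("feature counts must be >= 1")
    }
    if (k_states < 2) stopf("k_states must be >= 2")
    if (k_states > min(n_taxa_nasal, n_taxa_rectal, n_immune_pops)) {
      stopf("k_states (%d) exceeds the smallest feature count", k_states)
    }
    if (depth_range[1] < 1 || diff(depth_range) < 0) {
      stopf("depth_range must satisfy 1 <= min <= max")
    }
    if (min(inpatient_interval_days, outpatient_interval_days) < 1) {
      stopf("sampling intervals must be >= 1 day")
    }
    if (followup_days < max(inpatient_interval_days, outpatient_interval_days)) {
      stopf("followup shorter than one sampling interval")
    }
    if (length(trajectory_sd) != 2 || any(trajectory_sd < 0)) {
      stopf("trajectory_sd must be (intercept_sd, slope_sd) >= 0")
    }
    if (maturation_headroom < 1) stopf("maturation_headroom must be >= 1")
    if (length(prd_coefs) != 4) stopf("prd_coefs must have length 4")
  })
  structure(cfg, class = "sim_config")
}

# Deterministic, maturation-ordered state mean compositions: feature j sits
# at position (j-.5)/J on a maturation axis, state k is a Gaussian bump
# centred at (k-.5)/K plus a small uniform floor, so consecutive states are
# distinct but share taxa, giving the gradual compositional succession that
# makes age predictable from composition.
state_means <- function(J, K) {
  u <- (seq_len(J) - 0.5) / J
  ctr <- (seq_len(K) - 0.5) / K
  w <- 0.6 / K
  m <- vapply(ctr, function(c) {
    v <- exp(-(u - c)^2 / (2 * w^2)) + 0.05 / J
    v / sum(v)
  }, numeric(J))
  t(m) # K x J
}

# Latent maturation of subject i at postmenstrual age pma (days):
#   m_i(t) = alpha_i + beta_i * log2(pma / 259)
# (259 days = 37 weeks, the term-equivalent anchor).
latent_maturation <- function(alpha, beta, pma_days) {
  alpha + beta * log2(pma_days / 259)
}

# Cumulative-logit thresholds evenly spaced over the maturation range.
# The axis extends `maturation_headroom`-fold past the followup horizon:
# compositional succession does not terminate at the end of observation, so
# the top state types are only entered, not saturated, within the study
# window (otherwise every fast-maturing subject parks in the final state
# and the maturation signal flattens).
ordinal_thresholds <- function(cfg) {
  pma_lo <- cfg$ga_range_weeks[1] * 7
  pma_hi <- (cfg$ga_range_weeks[2] * 7 + cfg$followup_days) *
    cfg$maturation_headroom
  m_lo <- log2(pma_lo / 259)
  m_hi <- log2(pma_hi / 259)
  m_lo + seq_len(cfg$k_states - 1) * (m_hi - m_lo) / cfg$k_states
}

draw_state <- function(m, tau, scale) {
  1L + sum(m + rlogis(1, 0, scale) > tau)
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates subjects, longitudinal microbiota count samples at two body
#' sites, immune compositions at three blood timepoints, clinical
#' covariates, and a binary respiratory outcome, with the full ground truth
#' (per-subject maturation intercept/slope, per-sample latent state type)
#' retained for recovery testing. Each subject is generated from an RNG
#' substream hashed from the master seed, so the output is bit-reproducible
#' and extending the cohort leaves existing subjects unchanged.
#'
#' @param config a [sim_config()].
#' @return `codevel_cohort`: list with `subjects` (one row per subject),
#'   `samples` (one row per collected sample), `features` (named list of
#'   sample x feature matrices: `nasal`, `rectal` integer counts;
#'   `immune_tphe`, `immune_ics` proportions), `truth`, and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  K <- cfg$k_states
  tau <- ordinal_thresholds(cfg)
  means <- list(
    nasal = state_means(cfg$n_taxa_nasal, K),
    rectal = state_means(cfg$n_taxa_rectal, K),
    immune_tphe = state_means(cfg$n_immune_pops, K),
    immune_ics = state_means(cfg$n_immune_pops, K)
  )
  taxa_ids <- list(
    nasal = sprintf("nas_t%02d", seq_len(cfg$n_taxa_nasal)),
    rectal = sprintf("rec_t%02d", seq_len(cfg$n_taxa_rectal)),
    immune_tphe = sprintf("tphe_p%02d", seq_len(cfg$n_immune_pops)),
    immune_ics = sprintf("ics_p%02d", seq_len(cfg$n_immune_pops))
  )

  subj_rows <- vector("list", cfg$n_subjects)
  samp_rows <- vector("list", cfg$n_subjects)
  feat_rows <- list(nasal = list(), rectal = list(),
                    immune_tphe = list(), immune_ics = list())
  truth_subj <- vector("list", cfg$n_subjects)
  latent <- list()

  for (i in seq_len(cfg$n_subjects)) {
    set.seed(substream_seed(cfg$seed, i))
    sid <- sprintf("S%04d", i)
    preterm <- runif(1) < cfg$preterm_fraction
    ga <- if (preterm && cfg$ga_range_weeks[1] < 37) {
      runif(1, cfg$ga_range_weeks[1], min(37, cfg$ga_range_weeks[2]))
    } else {
      runif(1, max(37, cfg$ga_range_weeks[1]), cfg$ga_range_weeks[2])
    }
    preterm <- ga < 37
    discharge_dol <- if (preterm) {
      max(2, round((rnorm(1, 38.5, 1) - ga) * 7))
    } else {
      sample(2:4, 1)
    }
    alpha_i <- rnorm(1, 0, cfg$trajectory_sd[1])
    beta_i <- rnorm(1, 1, cfg$trajectory_sd[2])

    covs <- list(
      delivery_mode = if (runif(1) < (if (preterm) 0.63 else 0.41))
        "cesarean" else "vaginal",
      sex = if (runif(1) < 0.45) "F" else "M",
      race = if (runif(1) < 0.29) "black_asian" else "other",
      milk_any = runif(1) < (if (preterm) 0.90 else 0.77),
      milk_months_gt50pct =
        round(pmax(0, rnorm(1, if (preterm) 5.4 else 3.0,
                            if (preterm) 4.5 else 3.5)), 1),
      abx_inpatient_days = if (preterm) rpois(1, 12) else 0L,
      abx_outpatient_courses = rpois(1, if (preterm) 1.1 else 0.6),
      maternal_abx = runif(1) < 0.4,
      chorioamnionitis = runif(1) < (if (preterm) 0.047 else 0.034),
      rom_gt18h = runif(1) < 0.15,
      cmv_positive = runif(1) < 0.08,
      birthweight = round(if (preterm) {
        max(400, rnorm(1, 1400 + (ga - 30) * 120, 350))
      } else {
        max(2000, rnorm(1, 3470, 510))
      }),
      maternal_education = sample(c("hs", "some_college", "college", "grad"), 1),
      season = sample(c("winter", "spring", "summer", "fall"), 1),
      fio2_14d = if (preterm) round(21 + abs(rnorm(1, 0, 4)), 1) else 21
    )

    # inpatient series from DOL 3; term infants discharged earlier still get
    # an enrollment sample at DOL 3
    dols_in <- seq(3L, max(discharge_dol, 3L),
                   by = cfg$inpatient_interval_days)
    dols_in <- dols_in[dols_in <= max(discharge_dol, 3L)]
    dols_out <- seq(discharge_dol + cfg$outpatient_interval_days,
                    cfg$followup_days, by = cfg$outpatient_interval_days)
    dols <- sort(unique(c(dols_in, dols_out)))

    rows <- list()
    for (site in c("nasal", "rectal")) {
      for (dol in dols) {
        if (runif(1) < cfg$site_missing_rate) next
        pma <- ga * 7 + dol
        st <- draw_state(latent_maturation(alpha_i, beta_i, pma), tau,
                         cfg$ordinal_scale)
        depth <- cfg$depth_range[1] +
          sample.int(cfg$depth_range[2] - cfg$depth_range[1] + 1L, 1L) - 1L
        p <- rdirichlet1(cfg$state_concentration * means[[site]][st, ])
        x <- as.integer(rmultinom(1, depth, p))
        ill <- runif(1) < (0.02 + 0.05 * (st - 1) / (K - 1))
        samp_id <- sprintf("%s_%s_%04d", sid, substr(site, 1, 3), dol)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = samp_id, subject_id = sid, site = site, dol = dol,
          pma_days = pma, timepoint = NA_character_, illness = ill,
          stringsAsFactors = FALSE)
        feat_rows[[site]][[samp_id]] <- x
        latent[[samp_id]] <- st
      }
    }

    tp_dol <- c(birth = 0L, discharge = discharge_dol, one_year = 365L)
    for (tp in names(tp_dol)) {
      present <- runif(1) >= cfg$immune_missing_rate
      pma <- ga * 7 + tp_dol[[tp]]
      for (assay in c("immune_tphe", "immune_ics")) {
        st <- draw_state(latent_maturation(alpha_i, beta_i, max(pma, 1)), tau,
                         cfg$ordinal_scale)
        comp <- rdirichlet1(cfg$state_concentration * means[[assay]][st, ])
        if (!present) next
        samp_id <- sprintf("%s_%s_%s", sid, sub("immune_", "", assay), tp)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = samp_id, subject_id = sid, site = assay,
          dol = tp_dol[[tp]], pma_days = pma, timepoint = tp,
          illness = FALSE, stringsAsFactors = FALSE)
        feat_rows[[assay]][[samp_id]] <- comp
        latent[[samp_id]] <- st
      }
    }

    z <- c(alpha_i / max(cfg$trajectory_sd[1], 1e-8),
           (beta_i - 1) / max(cfg$trajectory_sd[2], 1e-8))
    di_true <- c(z[1], z[2], z[1], z[2])
    prd_prob <- plogis(cfg$prd_intercept + sum(cfg$prd_coefs * di_true))
    prd <- runif(1) < prd_prob

    subj_rows[[i]] <- cbind(
      data.frame(subject_id = sid, ga_birth = ga, preterm = preterm,
                 discharge_dol = discharge_dol, stringsAsFactors = FALSE),
      as.data.frame(covs, stringsAsFactors = FALSE),
      data.frame(prd = prd))
    truth_subj[[i]] <- data.frame(
      subject_id = sid, alpha = alpha_i, beta = beta_i,
      prd_prob = prd_prob, stringsAsFactors = FALSE)
    samp_rows[[i]] <- do.call(rbind, rows)
  }

  subjects <- do.call(rbind, subj_rows)
  samples <- do.call(rbind, samp_rows)
  rownames(samples) <- NULL
  features <- lapply(names(feat_rows), function(site) {
    lst <- feat_rows[[site]]
    if (length(lst) == 0) {
      return(matrix(numeric(0), 0, length(taxa_ids[[site]]),
                    dimnames = list(NULL, taxa_ids[[site]])))
    }
    m <- do.call(rbind, lst)
    dimnames(m) <- list(names(lst), taxa_ids[[site]])
    m
  })
  names(features) <- names(feat_rows)

  structure(list(
    subjects = subjects, samples = samples, features = features,
    truth = list(
      subjects = do.call(rbind, truth_subj),
      latent_state = unlist(latent),
      thresholds = tau, state_means = means
    ),
    config = cfg
  ), class = "codevel_cohort")
}

#' @export
print.codevel_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects (%d preterm), %d samples\n",
    nrow(x$subjects), sum(x$subjects$preterm), nrow(x$samples)))
  print(table(x$samples$site))
  invisible(x)
}

#' Per-subject ground truth of a synthetic cohort
#'
#' Extracts the generating quantities for recovery tests: each subject's
#' maturation intercept and slope, outcome probability, and the days spent
#' in each latent nasal state type (midpoint-interval allocation over the
#' collected nasal samples, matching the observed-duration construction).
#'
#' @param cohort a `codevel_cohort` with its truth block.
#' @return data.frame, one row per subject: `alpha`, `beta`, `prd_prob`,
#'   `observed_span`, and `state_days_k` columns summing to the span.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "codevel_cohort"))
  if (is.null(cohort$truth)) stopf("cohort carries no truth block")
  tr <- cohort$truth$subjects
  nas <- cohort$samples[cohort$samples$site == "nasal", ]
  K <- cohort$config$k_states
  days <- matrix(0, nrow(tr), K,
                 dimnames = list(tr$subject_id, paste0("state_days_", 1:K)))
  span <- setNames(numeric(nrow(tr)), tr$subject_id)
  for (sid in tr$subject_id) {
    s <- nas[nas$subject_id == sid, ]
    if (nrow(s) < 2) next
    st <- cohort$truth$latent_state[s$sample_id]
    iv <- midpoint_intervals(s$dol, st)
    for (r in seq_len(nrow(iv))) {
      days[sid, iv$state[r]] <- days[sid, iv$state[r]] + iv$days[r]
    }
    span[sid] <- sum(iv$days)
  }
  cbind(tr, observed_span = span[tr$subject_id],
        as.data.frame(days[tr$subject_id, , drop = FALSE]))
}
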