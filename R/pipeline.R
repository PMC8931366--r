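#' Run the full co-development analysis pipeline
#'
#' Drives every stage end to end: cohort simulation (or loading), state-type
#' discovery per body site and immune assay (prevalence filter, depth
#' normalization, Laplace-evidence model selection, PMA enumeration),
#' compositional variance partitioning, state enrichment and exposure
#' models, the days-in-state table and quasi-Poisson association scan, the
#' elastic-net/BLUP Developmental Index, and random-forest outcome
#' prediction. Every output file carries the seed and configuration hash;
#' stage timings and filter counts are logged. A stage failure halts the
#' run naming the stage, with earlier outputs already persisted.
#'
#' @param config a `run_config` (see [read_run_config()]), a path to a YAML
#'   config, or a plain list of overrides.
#' @return Invisibly, a list bundle with elements `cohort`, `states`,
#'   `variance`, `enrichment`, `exposures`, `durations`, `scan`,
#'   `dev_index`, `outcome`, `timings`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("codevel seed=%d config=%s", cfg$seed, config_hash(unclass(cfg)))
  timings <- list()
  bundle <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    msg(cfg$verbose, "[%s] done in %.1fs", stage, timings[[stage]])
    out
  }

  cohort <- tick("cohort", {
    if (length(cfg$paths) > 0 && length(cfg$simulate) == 0) {
      load_cohort(cfg$paths)
    } else {
      sc <- do.call(sim_config, modifyList(cfg$simulate, list(seed = cfg$seed)))
      co <- generate_cohort(sc)
      write_cohort(co, file.path(cfg$out_dir, "data"))
      co
    }
  })
  bundle$cohort <- cohort

  sm <- cfg$state_models
  depth_of <- c(nasal = sm$depth_nasal, rectal = sm$depth_rectal,
                immune_tphe = sm$depth_immune, immune_ics = sm$depth_immune)
  systems <- names(cohort$features)[vapply(cohort$features, nrow, 1L) > 0]
  states <- tick("fit_states", {
    out <- list()
    for (sys in systems) {
      feat <- cohort$features[[sys]]
      kept <- filter_prevalence(feat, sm$min_prevalence)
      msg(cfg$verbose, "  %s: %d/%d features pass %.0f%% prevalence",
          sys, ncol(kept), ncol(feat), 100 * sm$min_prevalence)
      counts <- normalize_counts(kept, depth_of[[sys]])
      sel <- select_k(counts, k_range = sm$k_range[1]:sm$k_range[2],
                      seed = substream_seed(cfg$seed, match(sys, systems)))
      smp <- cohort$samples[match(rownames(counts), cohort$samples$sample_id), ]
      asg <- assign_and_enumerate(sel$best_fit, counts, smp$pma_days)
      write_tsv(data.frame(sample_id = rownames(counts), state = asg$label,
                           max_posterior = apply(asg$posterior, 1, max)),
                file.path(cfg$out_dir, paste0("states_", sys, ".tsv")), hdr)
      out[[sys]] <- list(selection = sel, assignment = asg, samples = smp,
                         counts = counts)
    }
    out
  })
  bundle$states <- states

  bundle$variance <- tick("variance", {
    vp <- variance_pairs(cohort, cfg$variance$var_threshold)
    write_tsv(vp, file.path(cfg$out_dir, "variance_partition.tsv"), hdr)
    vp
  })

  bundle$enrichment <- tick("enrichment", {
    out <- list()
    for (sys in names(states)) {
      st <- states[[sys]]
      out[[sys]] <- enrichment_by_term(st$assignment$label,
                                       st$samples$subject_id, cohort$subjects)
      out[[sys]]$system <- sys
    }
    res <- do.call(rbind, out)
    write_tsv(res, file.path(cfg$out_dir, "enrichment.tsv"), hdr)
    res
  })

  if ("immune_tphe" %in% names(states)) {
    bundle$exposures <- tick("exposures", {
      st <- states$immune_tphe
      sub <- cohort$subjects
      res <- list()
      for (k in sort(unique(st$assignment$label))) {
        ever_ids <- unique(st$samples$subject_id[st$assignment$label == k])
        ever <- sub$subject_id %in% ever_ids
        if (length(unique(ever)) < 2) next
        r <- exposure_model(
          ever,
          sub[, c("maternal_abx", "chorioamnionitis", "rom_gt18h",
                  "cmv_positive")],
          ga = sub$ga_birth,
          confounders = sub[, c("delivery_mode", "race", "sex")],
          fdr_level = cfg$associations$fdr_level)
        r$state <- k
        res[[as.character(k)]] <- r
      }
      res <- do.call(rbind, res)
      write_tsv(res, file.path(cfg$out_dir, "exposures.tsv"), hdr)
      res
    })
  }

  nasal_states <- states[["nasal"]]
  bundle$durations <- tick("durations", {
    sdf <- data.frame(subject_id = nasal_states$samples$subject_id,
                      dol = nasal_states$samples$dol,
                      state = nasal_states$assignment$label)
    dur <- build_durations(sdf)
    dd <- setNames(cohort$subjects$discharge_dol, cohort$subjects$subject_id)
    dur <- apply_inclusion(dur, sdf, dd)
    msg(cfg$verbose, "  %d/%d subjects pass inclusion",
        sum(dur$included), length(dur$included))
    write_tsv(durations_as_df(dur), file.path(cfg$out_dir, "durations.tsv"),
              hdr)
    dur
  })

  bundle$scan <- tick("association_scan", {
    vois <- immune_voi_tables(cohort)
    res <- association_scan(bundle$durations, vois, cohort$subjects,
                            fdr_level = cfg$associations$fdr_level)
    write_tsv(res, file.path(cfg$out_dir, "associations.tsv"), hdr)
    res
  })

  di_cfg <- cfg$dev_index
  bundle$dev_index <- tick("dev_index", {
    trajs <- list()
    for (sys in c("microbiome", "immune")) {
      have <- if (sys == "microbiome") c("nasal", "rectal") else
        c("immune_tphe", "immune_ics")
      if (!any(have %in% systems)) {
        msg(cfg$verbose, "  no %s tables; DI restricted", sys)
        next
      }
      fb <- assemble_features(cohort, sys, max_dol = di_cfg$max_dol,
                              min_taxa_prevalence = di_cfg$min_taxa_prevalence)
      pred <- tune_and_predict(fb, seed = substream_seed(cfg$seed, 101 +
                                                          (sys == "immune")),
                               n_draws = di_cfg$n_draws)
      msg(cfg$verbose, "  %s: held-out R2 = %.3f (alpha %.2f, lambda %.3f)",
          sys, pred$r2, pred$alpha, pred$lambda)
      write_tsv(pred$predictions,
                file.path(cfg$out_dir, paste0("pma_pred_", sys, ".tsv")), hdr)
      trajs[[sys]] <- fit_trajectories(pred)
    }
    di <- if (length(trajs) == 2) {
      developmental_index(trajs$microbiome, trajs$immune)
    } else if (length(trajs) == 1) {
      t1 <- trajs[[1]]
      data.frame(subject = t1$subject,
                 micro_z_alpha = t1$z_alpha, micro_z_beta = t1$z_beta)
    } else {
      stopf("no system had usable features")
    }
    write_tsv(di, file.path(cfg$out_dir, "developmental_index.tsv"), hdr)
    list(trajectories = trajs, di = di)
  })

  bundle$outcome <- tick("outcome", {
    sub <- cohort$subjects
    di <- bundle$dev_index$di
    di_x <- as.matrix(di[match(sub$subject_id, di$subject), -1, drop = FALSE])
    clin_x <- clinical_features(sub)
    y <- as.integer(sub$prd)
    oc <- cfg$outcome
    res <- list()
    sets <- list(clinical = clin_x, di = di_x,
                 combined = cbind(clin_x, di_x))
    for (nm in names(sets)) {
      tuned <- rf_tune(sets[[nm]], y, seed = substream_seed(cfg$seed, 201),
                       n_draws = oc$n_draws)
      res[[nm]] <- rf_evaluate(sets[[nm]], y, tuned,
                               seed = substream_seed(cfg$seed, 202),
                               folds = oc$eval_folds)
      msg(cfg$verbose, "  %s features: mean AUC = %.3f +/- %.3f",
          nm, res[[nm]]$mean_auc, res[[nm]]$se_auc)
    }
    if (all(c("micro_z_alpha", "immune_z_beta") %in% colnames(di_x))) {
      pd <- partial_dependence(res$di$model, di_x,
                               c("micro_z_alpha", "immune_z_beta"))
      write_tsv(pd, file.path(cfg$out_dir, "partial_dependence.tsv"), hdr)
      res$partial_dependence <- pd
    }
    auc_df <- data.frame(
      feature_set = setdiff(names(res), "partial_dependence"),
      mean_auc = vapply(res[setdiff(names(res), "partial_dependence")],
                        function(r) r$mean_auc, numeric(1)),
      se_auc = vapply(res[setdiff(names(res), "partial_dependence")],
                      function(r) r$se_auc, numeric(1)))
    write_tsv(auc_df, file.path(cfg$out_dir, "prd_auc.tsv"), hdr)
    res
  })

  bundle$timings <- timings
  invisible(bundle)
}

durations_as_df <- function(dur) {
  long <- expand.grid(subject_id = rownames(dur$days),
                      state = colnames(dur$days), stringsAsFactors = FALSE)
  long$days <- dur$days[cbind(long$subject_id, long$state)]
  long$included <- dur$included[long$subject_id]
  long$reason <- dur$reason[long$subject_id]
  long[order(long$subject_id, long$state), ]
}

# Per-timepoint immune VOI matrices (subjects x populations, both assays).
immune_voi_tables <- function(cohort) {
  out <- list()
  smp <- cohort$samples
  for (tp in c("birth", "discharge", "one_year")) {
    mats <- list()
    for (assay in c("immune_tphe", "immune_ics")) {
      s <- smp[smp$site == assay & !is.na(smp$timepoint) &
                 smp$timepoint == tp, ]
      if (nrow(s) == 0) next
      m <- cohort$features[[assay]][s$sample_id, , drop = FALSE]
      rownames(m) <- s$subject_id
      mats[[assay]] <- m
    }
    if (length(mats) > 0) {
      sids <- unique(unlist(lapply(mats, rownames)))
      full <- do.call(cbind, lapply(mats, function(m) {
        o <- matrix(NA_real_, length(sids), ncol(m),
                    dimnames = list(sids, colnames(m)))
        o[rownames(m), ] <- m
        o
      }))
      out[[tp]] <- full
    }
  }
  out
}

clinical_features <- function(sub) {
  cbind(
    race = as.numeric(factor(sub$race)),
    maternal_education = as.numeric(factor(sub$maternal_education)),
    sex = as.numeric(sub$sex == "F"),
    ga_birth = sub$ga_birth,
    birthweight = sub$birthweight,
    season = as.numeric(factor(sub$season)),
    fio2_14d = sub$fio2_14d)
}

# Cross-system and age variance partitioning on matched samples.
variance_pairs <- function(cohort, var_threshold = 1e-4) {
  smp <- cohort$samples
  sub <- cohort$subjects
  rownames(sub) <- sub$subject_id
  rows <- list()
  add <- function(pair, adjustment, mv) {
    rows[[length(rows) + 1]] <<- data.frame(
      pair = pair, adjustment = adjustment, r2_adj = mv$r2_adj,
      wilks_p = mv$p_value, bic = mv$bic, n = mv$n, stringsAsFactors = FALSE)
  }
  for (site in c("nasal", "rectal")) {
    s <- smp[smp$site == site, ]
    if (nrow(s) < 30) next
    feat <- cohort$features[[site]][s$sample_id, , drop = FALSE]
    prop <- feat / pmax(rowSums(feat), 1)
    Y <- prepare_block(prop, var_threshold)
    preterm <- sub[s$subject_id, "ga_birth"] < 37
    base <- data.frame(preterm = as.numeric(preterm))
    for (agev in c("pma", "dol")) {
      Xf <- cbind(base, age = if (agev == "pma") log2(s$pma_days) else
        log2(s$dol + 1))
      add(paste0(site, "~", agev), "preterm",
          manova_r2(Y, Xf, base))
    }
  }
  # cross-system: immune composition vs nasal composition, matched by
  # subject and nearest sampling day (within 30 days)
  imm <- smp[smp$site == "immune_tphe", ]
  nas <- smp[smp$site == "nasal", ]
  if (nrow(imm) >= 30 && nrow(nas) >= 30) {
    match_idx <- vapply(seq_len(nrow(imm)), function(i) {
      cand <- which(nas$subject_id == imm$subject_id[i])
      if (length(cand) == 0) return(NA_integer_)
      d <- abs(nas$dol[cand] - imm$dol[i])
      if (min(d) > 30) return(NA_integer_)
      cand[which.min(d)]
    }, integer(1))
    ok <- !is.na(match_idx)
    if (sum(ok) >= 30) {
      imm_m <- cohort$features$immune_tphe[imm$sample_id[ok], , drop = FALSE]
      nas_m <- cohort$features$nasal[nas$sample_id[match_idx[ok]], ,
                                     drop = FALSE]
      nas_p <- nas_m / pmax(rowSums(nas_m), 1)
      Y <- prepare_block(imm_m, var_threshold)
      X <- as.data.frame(prepare_block(nas_p, var_threshold))
      names(X) <- paste0("x", seq_along(X))
      preterm <- data.frame(
        preterm = as.numeric(sub[imm$subject_id[ok], "ga_birth"] < 37))
      pma <- log2(imm$pma_days[ok])
      full_un <- cbind(preterm, X)
      add("tcell~nasal", "preterm", manova_r2(Y, full_un, preterm))
      full_ad <- cbind(preterm, pma = pma, X)
      red_ad <- cbind(preterm, pma = pma)
      add("tcell~nasal", "preterm+pma", manova_r2(Y, full_ad, red_ad))
    }
  }
  do.call(rbind, rows)
}

# Load a cohort from on-disk tables (the inverse of write_cohort; the truth
# block is absent for real data).
load_cohort <- function(paths) {
  subjects <- read.delim(paths$subjects, comment.char = "#",
                         stringsAsFactors = FALSE)
  samples <- read.delim(paths$samples, comment.char = "#",
                        stringsAsFactors = FALSE)
  features <- list()
  if (!is.null(paths$counts_nasal)) {
    features$nasal <- read_counts(paths$counts_nasal)
  }
  if (!is.null(paths$counts_rectal)) {
    features$rectal <- read_counts(paths$counts_rectal)
  }
  for (assay in c("immune_tphe", "immune_ics")) {
    if (!is.null(paths[[assay]])) {
      df <- utils::read.csv(paths[[assay]], check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      features[[assay]] <- m
    }
  }
  structure(list(subjects = subjects, samples = samples, features = features,
                 truth = NULL, config = list(seed = NA_integer_)),
            class = "codevel_cohort")
}
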