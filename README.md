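# codevel

Longitudinal analysis of microbiota–T cell co-development in preterm and
full-term infants.

## The problem

In mixed preterm/full-term birth cohorts, both the mucosal microbiota and
the circulating T cell compartment reorganize dramatically over the first
year of life, and much of that reorganization tracks **postmenstrual age**
(PMA = gestational age at birth + postnatal age) rather than time since
birth. `codevel` implements an analysis chain for cohorts in which nasal and
rectal 16S count tables are collected weekly in hospital and monthly after
discharge, and T cell population relative abundances (from flow-cytometry
clustering) are measured at birth, discharge and one year:

1. **State types** — Dirichlet-multinomial mixtures (DMM) cluster samples
   into community state types (CSTs) and immune state types (ISTs);
   the number of components minimizes the Laplace approximation of the
   negative log model evidence over K = 1..20, and states are enumerated by
   the average PMA at which they occur.
2. **Variance partitioning** — compositional multivariate ANOVA on
   isometric log-ratio coordinates reports
   `R²_adj = 1 − MSE_full / MSE_reduced` between systems, with Wilks'
   lambda tests, before and after adjusting for age.
3. **Associations** — logistic mixed models test state enrichment by
   gestational age; joint logistic exposure models (with a smooth GA term
   and Firth fallback under separation) test perinatal exposures at 10%
   FDR.
4. **Duration axis** — days spent in each state (midpoint intervals
   between state change points, 14-day birth rule, half-gap tail) feed a
   quasi-Poisson scan of every state × immune-variable × timepoint triple,
   Benjamini–Hochberg corrected at 10% FDR.
5. **Developmental Index (DI)** — subject-held-out elastic nets predict
   `log2(PMA)` from composition; the mixed model
   `ŷ − log2(37) ~ log2(PMA/37) + (1 + log2(PMA/37) | subject)` yields
   per-subject BLUP 37-week intercepts and maturation slopes, z-scored by
   their conditional standard errors — four features per subject.
6. **Outcome** — tuned random forests compare the DI against clinical risk
   factors for persistent respiratory disease (PRD), with per-fold AUCs and
   two-feature partial-dependence surfaces.

A seeded synthetic cohort generator with full ground truth
(`generate_cohort`) underpins the test suite: parameter-recovery,
FDR-calibration, leakage and determinism checks all run against it.

## Worked example

```r
library(codevel)
cohort <- generate_cohort(sim_config(n_subjects = 60, seed = 42))
#> Synthetic cohort: 60 subjects (30 preterm), 2367 samples

counts <- filter_prevalence(cohort$features$nasal, 0.05)
norm   <- normalize_counts(counts / rowSums(counts), 1200)
sel    <- select_k(norm, k_range = 1:8, seed = 42)
nas    <- cohort$samples[match(rownames(norm), cohort$samples$sample_id), ]
states <- assign_and_enumerate(sel$best_fit, norm, nas$pma_days)
sel$best_fit
#> Dirichlet-multinomial mixture: K = 8, J = 30 features
#>   log-likelihood -2247613.19 after 3 EM iterations (converged)
#>   Laplace negative log evidence 2248318.76
#>   weights: 0.103 0.095 0.251 0.080 0.104 0.138 0.115 0.112
round(states$mean_pma_per_state / 7, 1)
#> [1] 31.4 35.8 42.0 51.0 64.6 78.3 81.6 91.0
```

Eight nasal state types are selected on this 60-subject cohort, and after
enumeration their mean PMA rises monotonically from 31 to 91 weeks — the
state ladder is an age axis. Predicting age back from composition:

```r
fb   <- assemble_features(cohort, "microbiome")
pred <- tune_and_predict(fb, seed = 42, n_draws = 25)
pred
#> microbiome PMA prediction: 1084 samples, alpha = 0.117, lambda = 0.0197
#>   held-out R2 = 0.799 (back-transformed), 0.837 (log2 scale)

traj <- fit_trajectories(pred)
head(traj[, c("subject", "alpha", "beta", "z_alpha", "z_beta")], 3)
#>   subject        alpha      beta    z_alpha   z_beta
#> 1   S0001 -0.013214361 0.8093293 -4.1475383 0.276288
#> 2   S0002  0.003942714 0.8656827 -2.1479291 1.106459
#> 3   S0003  0.111442616 0.8452998 -0.7442124 1.193924
```

The held-out R² of 0.80 says composition alone dates a sample to within a
narrow PMA window. Subject S0001's `alpha = -0.013` means its predicted age
at term-equivalent (37 weeks) runs about 1% of a log2-fold *behind* its true
age — a slightly immature microbiome — and `z_alpha = -4.1` says that lag is
over four conditional standard errors below the cohort median; `beta < 1`
indicates slower-than-average maturation over the first year.

The full chain — state typing of all four systems, variance partitioning,
enrichment, the duration scan, both DI systems and PRD prediction — runs
from one configuration:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "codevel"))
bundle <- run_pipeline(cfg)
```

Every output lands in `cfg$out_dir` as a TSV stamped with the seed and a
configuration hash; reruns are byte-identical. A thin command-line driver
with the same stages ships at `inst/cli/codevel`
(`codevel run-all --config my.yaml`).

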