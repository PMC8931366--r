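# Independent oracles used across the suite. Each is deliberately naive:
# enumeration or day-by-day bookkeeping, never the package's own code path.

# Polya-urn check of the DM log density by brute-force enumeration of draw
# orderings: each sequence's probability is the product of sequential urn
# probabilities (alpha_j + seen_j) / (A + draws_so_far). The urn is
# exchangeable, so every ordering carries the same probability and the
# density of one ordered sequence is the summed probability divided by the
# number of enumerated orderings.
polya_urn_logprob <- function(x, alpha) {
  N <- sum(x)
  if (N == 0) return(0)
  A <- sum(alpha)
  total <- 0
  n_orderings <- 0
  recurse <- function(remaining, seen, prob) {
    draws <- sum(seen)
    if (draws == N) {
      total <<- total + prob
      n_orderings <<- n_orderings + 1
      return(invisible())
    }
    for (j in seq_along(remaining)) {
      if (remaining[j] > 0) {
        pj <- (alpha[j] + seen[j]) / (A + draws)
        rem <- remaining
        rem[j] <- rem[j] - 1
        sn <- seen
        sn[j] <- sn[j] + 1
        recurse(rem, sn, prob * pj)
      }
    }
  }
  recurse(x, rep(0, length(x)), 1)
  log(total) - log(n_orderings)
}

# Day-by-day duration oracle: split the observation span into half-day
# cells and hand each cell to the sample nearest its centre (ties go to the
# earlier sample). Cell centres sit at quarter-days so they never coincide
# with inter-sample midpoints.
daily_duration_oracle <- function(dol, state, first_day_rule = 14) {
  n <- length(dol)
  stopifnot(n >= 2)
  start <- if (dol[1] <= first_day_rule) 0 else (dol[1] + dol[2]) / 2
  end <- dol[n] + (dol[n] - dol[n - 1]) / 2
  out <- setNames(rep(0, length(unique(state))), sort(unique(state)))
  if (end <= start) return(out)
  cells <- seq(start, end - 0.5, by = 0.5)
  for (cs in cells) {
    centre <- cs + 0.25
    j <- which.min(abs(dol - centre)) # which.min takes the earlier on ties
    out[[as.character(state[j])]] <- out[[as.character(state[j])]] + 0.5
  }
  out
}

# Shared mixture-count simulator for DMM tests: K well-separated
# maturation-ordered components at a given Dirichlet precision.
sim_dmm_counts <- function(K = 3, J = 30, n = 600, precision = 50,
                           depth = c(1000, 3000), seed = 1) {
  set.seed(seed)
  means <- codevel:::state_means(J, K)
  comp <- sample.int(K, n, replace = TRUE)
  X <- t(vapply(seq_len(n), function(i) {
    p <- rgamma(J, means[comp[i], ] * precision)
    p <- p / sum(p)
    rmultinom(1, sample(depth[1]:depth[2], 1), p)[, 1]
  }, numeric(J)))
  list(counts = X, component = comp)
}

# Small cohort defaults used when a full-size cohort is unnecessary.
small_cohort <- function(n = 40, seed = 7, ...) {
  generate_cohort(sim_config(n_subjects = n, seed = seed, ...))
}

# Seeded permutation of the prediction target (breaks the feature-age link
# while preserving the marginal distribution).
with_seed_perm <- function(x, subject, seed = 1) {
  set.seed(seed)
  sample(x)
}
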