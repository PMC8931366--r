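#' Dirichlet-multinomial log density
#'
#' Log probability of a count vector under the Dirichlet-multinomial
#' (multivariate Polya) distribution with parameter vector `alpha`:
#' \deqn{\log DM(x \mid \alpha) = \ln\Gamma(A) - \ln\Gamma(N + A) +
#'   \sum_j \left[\ln\Gamma(x_j + \alpha_j) - \ln\Gamma(\alpha_j)\right]}
#' with \eqn{A = \sum_j \alpha_j} and \eqn{N = \sum_j x_j}.
#'
#' @param x nonnegative integer count vector.
#' @param alpha strictly positive Dirichlet parameter vector, same length.
#' @return The log density (a finite scalar; 0 for the empty sample).
#' @examples
#' dirmult_loglik(c(1, 0), c(1, 1)) # log(1/2)
#' @export
dirmult_loglik <- function(x, alpha) {
  if (length(x) != length(alpha)) stopf("length(x) != length(alpha)")
  if (any(alpha <= 0)) stopf("alpha must be strictly positive")
  if (any(x < 0)) stopf("counts must be nonnegative")
  A <- sum(alpha)
  N <- sum(x)
  lgamma(A) - lgamma(N + A) + sum(lgamma(x + alpha) - lgamma(alpha))
}

# Per-row DM log density for a count matrix X (n x J) at one alpha vector
# (compiled; the R expression would be
#  lgamma(A) - lgamma(N + A) + rowSums(lgamma(X + alpha)) - sum(lgamma(alpha))).
dm_loglik_rows <- function(X, alpha, Nrow = rowSums(X)) {
  dm_rowll_cpp(X, alpha, Nrow)
}

# Weighted DM log-likelihood and gradient in log-alpha space, used by the
# M-step ascent. Gradient of sum_i w_i log DM(x_i|alpha) wrt log alpha_j is
# alpha_j * sum_i w_i [psi(A) - psi(N_i+A) + psi(x_ij+alpha_j) - psi(alpha_j)].
dm_wobj <- function(la, X, w, Nrow) {
  alpha <- exp(la)
  -sum(w * dm_loglik_rows(X, alpha, Nrow))
}
dm_wgrad <- function(la, X, w, Nrow) {
  alpha <- exp(la)
  A <- sum(alpha)
  sw <- sum(w)
  g_common <- sw * digamma(A) - sum(w * digamma(Nrow + A))
  g_j <- colSums(w * digamma(sweep(X, 2, alpha, "+"))) - sw * digamma(alpha)
  -(alpha * (g_common + g_j))
}

# Moment-style initial alpha from responsibility-weighted proportions.
init_alpha <- function(P, w) {
  w <- w / sum(w)
  pbar <- colSums(P * w)
  pbar <- pmax(pbar, 1e-6)
  pbar <- pbar / sum(pbar)
  v <- colSums(w * sweep(P, 2, pbar, "-")^2)
  ok <- v > 1e-12 & pbar > 1e-4
  s <- if (any(ok)) median(pbar[ok] * (1 - pbar[ok]) / v[ok] - 1) else ncol(P)
  s <- min(max(s, 1), 1e4)
  pbar * s
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Expectation-maximization for a K-component Dirichlet-multinomial mixture
#' over a samples-by-features count matrix. Responsibilities are seeded by
#' k-means on the row proportions; the M-step performs quasi-Newton ascent on
#' the component log-alpha vectors with the analytic digamma gradient, so each
#' iteration is a generalized EM step and the observed-data log-likelihood is
#' non-decreasing. The Laplace approximation of the negative log model
#' evidence is recorded for model selection across K.
#'
#' @param counts integer matrix, samples x features (e.g. from
#'   [normalize_counts()]); rows with zero total are allowed.
#' @param K number of mixture components (1 <= K <= nrow(counts)).
#' @param seed integer seed controlling initialization and restarts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations.
#' @param restarts attempts from fresh seeds if a component degenerates.
#' @param verbose emit progress messages.
#' @return An object of class `codevel_dmm`: list with `K`, `alpha` (K x J),
#'   `pi`, `loglik`, `loglik_trace`, `neg_log_evidence`, `n_iter`,
#'   `converged`, `feature_ids`, `sample_ids`.
#' @seealso [select_k()], [assign_and_enumerate()], [dirmult_loglik()]
#' @export
fit_dmm <- function(counts, K, seed = 1L, tol = 1e-6, max_iter = 1000L,
                    restarts = 3L, verbose = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  J <- ncol(counts)
  if (K < 1) stopf("K must be >= 1")
  if (K > n) stopf("K = %d exceeds the number of samples (%d)", K, n)
  last_err <- NULL
  for (attempt in seq_len(restarts)) {
    fit <- tryCatch(
      fit_dmm_once(counts, K, substream_seed(seed, attempt - 1L), tol,
                   max_iter, verbose),
      error = function(e) e
    )
    if (!inherits(fit, "error")) {
      fit$seed <- seed
      fit$attempt <- attempt
      return(fit)
    }
    last_err <- fit
    msg(verbose, "fit_dmm K=%d attempt %d failed: %s", K, attempt,
        conditionMessage(last_err))
  }
  stopf("fit_dmm failed for K = %d after %d attempts (n = %d, J = %d): %s",
        K, restarts, n, J, conditionMessage(last_err))
}

fit_dmm_once <- function(X, K, seed, tol, max_iter, verbose) {
  n <- nrow(X)
  J <- ncol(X)
  Nrow <- rowSums(X)
  P <- X / pmax(Nrow, 1)

  r <- with_seed(seed, {
    if (K == 1) {
      matrix(1, n, 1)
    } else {
      km <- suppressWarnings(kmeans(P, centers = K, nstart = 5, iter.max = 50))
      r0 <- matrix(0.5 / (K - 1) * 0.1, n, K)
      r0[cbind(seq_len(n), km$cluster)] <- 1
      r0 / rowSums(r0)
    }
  })

  la <- matrix(0, K, J)
  for (k in seq_len(K)) la[k, ] <- log(init_alpha(P, r[, k]))
  pi_k <- colMeans(r)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  comp_ll <- matrix(0, n, K)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # M-step (generalized): warm-started bounded quasi-Newton ascent per
    # component. log-alpha is boxed to [-15, 9]: beyond ~e^9 per element the
    # DM likelihood is a flat ridge towards its multinomial limit and the
    # lgamma differences lose numerical meaning.
    for (k in seq_len(K)) {
      # rows with negligible responsibility contribute < 1e-10 * |ll| to the
      # weighted objective; dropping them leaves the generalized M-step
      # ascent intact within the monotonicity slack
      act <- which(r[, k] > 1e-10)
      opt <- optim(pmin(pmax(la[k, ], -15), 9), dm_wobj_cpp, dm_wgrad_cpp,
                   X = X[act, , drop = FALSE], w = r[act, k],
                   Nrow = Nrow[act],
                   method = "L-BFGS-B", lower = -15, upper = 9,
                   control = list(maxit = if (iter <= 2) 100L else 15L))
      la[k, ] <- opt$par
    }
    pi_k <- pmax(colMeans(r), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    # E-step
    for (k in seq_len(K)) comp_ll[, k] <- dm_loglik_rows(X, exp(la[k, ]), Nrow)
    lw <- sweep(comp_ll, 2, log(pi_k), "+")
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    r <- exp(lw - lse)
    if (any(colSums(r) < 1e-6)) {
      stopf("degenerate component (no responsibility mass) at iteration %d", iter)
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }

  alpha <- exp(la)
  structure(list(
    K = K, alpha = alpha, pi = pi_k, loglik = ll_old,
    loglik_trace = ll_trace,
    neg_log_evidence = dmm_neg_log_evidence(X, alpha, r, ll_old, Nrow),
    n_iter = iter, converged = converged,
    feature_ids = colnames(X), sample_ids = rownames(X)
  ), class = "codevel_dmm")
}

# Laplace approximation of the negative log model evidence:
#   -loglik(theta_hat) - P*ln(2*pi)/2 + (1/2) ln|H|
# with P = K*J free alpha parameters and H the block-diagonal (per component)
# Hessian of the negative log-likelihood in alpha, built from trigamma terms
# weighted by the posterior responsibilities:
#   H_k = c_k 11' + diag(d_kj),
#   c_k  = -sum_i r_ik [psi'(A_k) - psi'(N_i + A_k)]
#   d_kj = -sum_i r_ik [psi'(x_ij + alpha_kj) - psi'(alpha_kj)]
# ln|H_k| via the matrix determinant lemma. The mixture weights are treated
# as fixed at their MLE (they contribute no alpha-block terms).
dmm_neg_log_evidence <- function(X, alpha, r, loglik, Nrow = rowSums(X)) {
  K <- nrow(alpha)
  J <- ncol(alpha)
  logdet <- 0
  for (k in seq_len(K)) {
    a <- alpha[k, ]
    A <- sum(a)
    w <- r[, k]
    c_k <- -(sum(w) * trigamma(A) - sum(w * trigamma(Nrow + A)))
    d_kj <- -(colSums(w * trigamma(sweep(X, 2, a, "+"))) -
                sum(w) * trigamma(a))
    d_kj <- pmax(d_kj, 1e-10)
    lever <- 1 + c_k * sum(1 / d_kj)
    logdet <- logdet + sum(log(d_kj)) + log(max(lever, 1e-10))
  }
  P <- K * J
  -loglik - P * log(2 * pi) / 2 + 0.5 * logdet
}

#' Select the number of mixture components by Laplace evidence
#'
#' Fits [fit_dmm()] for each K in `k_range` and returns the K minimizing the
#' Laplace approximation of the negative log model evidence (ties break to
#' the smallest K). Individual fit failures are excluded with a warning;
#' selection fails only if all K fail.
#'
#' @inheritParams fit_dmm
#' @param k_range candidate component counts (default 1:20).
#' @return list with `best_k`, `best_fit`, `fits` (named list over K) and
#'   `evidence` (data.frame K x neg_log_evidence).
#' @export
select_k <- function(counts, k_range = 1:20, seed = 1L, tol = 1e-6,
                     max_iter = 1000L, verbose = FALSE) {
  if (length(k_range) == 0) stopf("k_range is empty")
  fits <- list()
  for (K in k_range) {
    f <- tryCatch(
      fit_dmm(counts, K, seed = substream_seed(seed, K), tol = tol,
              max_iter = max_iter, verbose = verbose),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      warnf("select_k: K = %d excluded (%s)", K, conditionMessage(f))
    } else {
      fits[[as.character(K)]] <- f
      msg(verbose, "select_k: K=%d nle=%.2f", K, f$neg_log_evidence)
    }
  }
  if (length(fits) == 0) stopf("select_k: all candidate K failed")
  nle <- vapply(fits, function(f) f$neg_log_evidence, numeric(1))
  ks <- as.integer(names(fits))
  best_k <- ks[which.min(nle)] # which.min takes first minimum; ks ascending
  list(best_k = best_k, best_fit = fits[[as.character(best_k)]], fits = fits,
       evidence = data.frame(K = ks, neg_log_evidence = unname(nle)))
}

#' Posterior state assignment enumerated by average PMA
#'
#' Computes each sample's posterior over the fitted mixture components, takes
#' the maximum-posterior hard label (ties to the lower label), and renumbers
#' components 1..K by ascending mean postmenstrual age of their assigned
#' samples, so state 1 is the earliest-occurring state type. Components with
#' no assigned samples keep a label, carry `NaN` mean PMA, and order last.
#'
#' @param fit a `codevel_dmm` object.
#' @param counts the count matrix the assignment is for (same features).
#' @param pma numeric vector of per-sample postmenstrual age (days).
#' @return `codevel_assignment`: list with `posterior` (samples x K, columns
#'   in enumerated order), `label` (integer vector), `mean_pma_per_state`,
#'   and `label_map` (fitted component -> enumerated label).
#' @export
assign_and_enumerate <- function(fit, counts, pma) {
  stopifnot(inherits(fit, "codevel_dmm"))
  counts <- as.matrix(counts)
  if (length(pma) != nrow(counts)) stopf("pma not aligned to samples")
  post <- predict(fit, counts)
  raw_label <- max.col(post, ties.method = "first")
  mean_pma <- vapply(seq_len(fit$K), function(k) {
    idx <- raw_label == k
    if (!any(idx)) NaN else mean(pma[idx])
  }, numeric(1))
  ord <- order(mean_pma, seq_len(fit$K), na.last = TRUE) # NaN-states last
  label_map <- integer(fit$K)
  label_map[ord] <- seq_len(fit$K)
  post_en <- post[, ord, drop = FALSE]
  colnames(post_en) <- paste0("state", seq_len(fit$K))
  structure(list(
    posterior = post_en,
    label = max.col(post_en, ties.method = "first"),
    mean_pma_per_state = mean_pma[ord],
    label_map = label_map
  ), class = "codevel_assignment")
}

#' @export
print.codevel_dmm <- function(x, ...) {
  cat(sprintf(
    "Dirichlet-multinomial mixture: K = %d, J = %d features\n", x$K,
    ncol(x$alpha)))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  Laplace negative log evidence %.2f\n", x$neg_log_evidence))
  cat("  weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.codevel_dmm <- function(object, ...) {
  structure(object$loglik, df = object$K * ncol(object$alpha) + object$K - 1,
            class = "logLik")
}

#' @export
coef.codevel_dmm <- function(object, ...) object$alpha

#' Posterior component probabilities for count data
#'
#' @param object a `codevel_dmm` fit.
#' @param newdata count matrix with the same features.
#' @param ... unused.
#' @return samples x K matrix of posterior probabilities (rows sum to 1).
#' @export
predict.codevel_dmm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$alpha)) stopf("feature dimension mismatch")
  Nrow <- rowSums(X)
  lw <- vapply(seq_len(object$K), function(k) {
    dm_loglik_rows(X, object$alpha[k, ], Nrow) + log(object$pi[k])
  }, numeric(nrow(X)))
  lw <- matrix(lw, nrow = nrow(X))
  mx <- apply(lw, 1, max)
  post <- exp(lw - mx)
  post / rowSums(post)
}

#' @export
summary.codevel_dmm <- function(object, ...) {
  comp_mean <- object$alpha / rowSums(object$alpha)
  out <- list(K = object$K, pi = object$pi, precision = rowSums(object$alpha),
              component_means = comp_mean, loglik = object$loglik,
              neg_log_evidence = object$neg_log_evidence)
  class(out) <- "summary.codevel_dmm"
  out
}

#' @export
print.summary.codevel_dmm <- function(x, ...) {
  cat(sprintf("DMM with %d components\n", x$K))
  df <- data.frame(weight = round(x$pi, 3), precision = round(x$precision, 1))
  print(df)
  invisible(x)
}

#' Simulate count samples from a fitted mixture
#'
#' @param object a `codevel_dmm` fit.
#' @param nsim number of samples.
#' @param seed optional integer seed.
#' @param depth sequencing depth per simulated sample (recycled).
#' @param ... unused.
#' @return list with `counts` (nsim x J) and `component` labels.
#' @export
simulate.codevel_dmm <- function(object, nsim = 1, seed = NULL,
                                 depth = 1000L, ...) {
  run <- function() {
    depth <- rep_len(depth, nsim)
    comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$pi)
    X <- t(vapply(seq_len(nsim), function(i) {
      p <- rdirichlet1(object$alpha[comp[i], ])
      as.numeric(rmultinom(1, depth[i], p))
    }, numeric(ncol(object$alpha))))
    colnames(X) <- object$feature_ids
    list(counts = X, component = comp)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
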