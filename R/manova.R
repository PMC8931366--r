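# Orthonormal sequential-binary (Helmert-type) ILR basis for J parts:
# columns are the normalized Helmert contrasts, so a uniform composition
# maps to the zero vector and the J-1 coordinates are unconstrained.
ilr_basis <- function(J) {
  H <- stats::contr.helmert(J) # J x (J-1)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Isometric log-ratio transform
#'
#' Maps a matrix of J-part compositions to J-1 unconstrained coordinates
#' using a fixed Helmert-type orthonormal basis. Rows must be strictly
#' positive (use [prepare_block()] for zero handling).
#'
#' @param comp samples x J matrix of positive compositions.
#' @return samples x (J-1) coordinate matrix.
#' @export
ilr_transform <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp <= 0)) stopf("ilr_transform requires strictly positive parts")
  comp <- comp / rowSums(comp)
  lc <- log(comp)
  clr <- lc - rowMeans(lc)
  clr %*% ilr_basis(ncol(comp))
}

#' Inverse isometric log-ratio transform
#'
#' @param z samples x (J-1) ILR coordinates from [ilr_transform()].
#' @return samples x J composition matrix (rows sum to 1).
#' @export
ilr_inverse <- function(z) {
  z <- as.matrix(z)
  V <- ilr_basis(ncol(z) + 1)
  clr <- z %*% t(V)
  e <- exp(clr)
  e / rowSums(e)
}

#' Prepare a compositional block for multivariate ANOVA
#'
#' Drops features with variance below `var_threshold`, renormalizes rows to
#' sum to one, replaces zeros by a multiplicative pseudocount (default: half
#' the smallest nonzero proportion in the block, renormalizing afterwards),
#' and applies the ILR transform.
#'
#' @param comp samples x features matrix of proportions (counts accepted,
#'   converted row-wise).
#' @param var_threshold features with variance below this are removed
#'   (default 1e-4).
#' @param pseudocount zero-replacement value; `NULL` (default) uses half
#'   the smallest nonzero proportion.
#' @return `IlrMatrix`: the samples x (J-1) coordinates with attributes
#'   `feature_ids` (retained features) and `pseudocount`.
#' @export
prepare_block <- function(comp, var_threshold = 1e-4, pseudocount = NULL) {
  m <- as.matrix(comp)
  if (any(m < 0)) stopf("negative entries in composition block")
  rs <- rowSums(m)
  if (any(rs == 0)) stopf("rows with zero total")
  m <- m / rs
  keep <- apply(m, 2, var) >= var_threshold
  if (sum(keep) < 2) {
    stopf("fewer than 2 features survive variance threshold %g", var_threshold)
  }
  m <- m[, keep, drop = FALSE]
  m <- m / rowSums(m)
  if (any(m == 0)) {
    if (is.null(pseudocount)) pseudocount <- min(m[m > 0]) / 2
    m[m == 0] <- pseudocount
    m <- m / rowSums(m)
  } else {
    pseudocount <- 0
  }
  out <- ilr_transform(m)
  attr(out, "feature_ids") <- colnames(comp)[keep]
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Variance explained between systems by multivariate ANOVA
#'
#' Fits nested multivariate linear models of an ILR-transformed response on
#' full and reduced predictor sets and reports the adjusted variance
#' explained \deqn{R^2_{adj} = 1 - MSE_{full} / MSE_{reduced}} where each
#' MSE is the total sum of squared residuals in the response matrix divided
#' by the residual degrees of freedom. Association is tested with Wilks'
#' lambda. Passing `predictors_reduced = NULL` compares against the
#' intercept-only model; an age-adjusted comparison puts the age variable in
#' both sets (reduced = age only).
#'
#' @param response numeric samples x q matrix (e.g. from [prepare_block()]).
#' @param predictors_full data.frame/matrix of predictors for the full model.
#' @param predictors_reduced subset of the full predictors (or `NULL`).
#' @return `codevel_manova`: list with `r2_adj`, `wilks_lambda`, `p_value`,
#'   `bic` (as printed: -2 loglik + n log p), `bic_alt` (textbook
#'   p log n penalty), `n`, `p_full`, `p_reduced`, `q`, and the two fits.
#' @export
manova_r2 <- function(response, predictors_full, predictors_reduced = NULL) {
  Y <- as.matrix(response)
  n <- nrow(Y)
  q <- ncol(Y)
  Xf <- as.data.frame(predictors_full)
  if (nrow(Xf) != n) stopf("predictor rows do not match response")
  if (!is.null(predictors_reduced)) {
    Xr <- as.data.frame(predictors_reduced)
    if (!all(names(Xr) %in% names(Xf))) {
      stopf("reduced predictors must be a subset of the full set")
    }
    if (length(names(Xr)) >= length(names(Xf))) {
      stopf("full predictor set must strictly contain the reduced set")
    }
  }
  fit_full <- fit_mlm(Y, Xf)
  fit_red <- if (is.null(predictors_reduced)) {
    fit_mlm(Y, NULL)
  } else {
    fit_mlm(Y, Xr)
  }
  if (n <= fit_full$rank) {
    stopf("n (%d) must exceed the full model's predictor rank (%d)",
          n, fit_full$rank)
  }
  mse_full <- fit_full$ssr / fit_full$df_res
  mse_red <- fit_red$ssr / fit_red$df_res
  r2_adj <- 1 - mse_full / mse_red

  wl <- tryCatch({
    a <- anova(fit_red$fit, fit_full$fit, test = "Wilks")
    list(lambda = a$Wilks[2], p = a$`Pr(>F)`[2])
  }, error = function(e) list(lambda = NA_real_, p = NA_real_))

  structure(list(
    r2_adj = r2_adj, wilks_lambda = wl$lambda, p_value = wl$p,
    bic = manova_bic(fit_full), bic_alt = manova_bic(fit_full, form = "plogn"),
    n = n, p_full = fit_full$p, p_reduced = fit_red$p, q = q,
    fit_full = fit_full, fit_reduced = fit_red
  ), class = "codevel_manova")
}

#' @export
print.codevel_manova <- function(x, ...) {
  cat(sprintf(
    "Multivariate ANOVA: n = %d, q = %d response dims\n  R2_adj = %.4f, Wilks lambda = %.4f (p = %.3g)\n  BIC = %.2f (printed n*log(p) penalty; p*log(n) form: %.2f)\n",
    x$n, x$q, x$r2_adj, x$wilks_lambda, x$p_value, x$bic, x$bic_alt))
  invisible(x)
}

# Multivariate linear fit bookkeeping. Aliased columns are dropped by lm()
# with a warning surfaced here; p counts estimated mean parameters
# (rank x response dimension).
fit_mlm <- function(Y, X) {
  if (is.null(X) || ncol(as.data.frame(X)) == 0) {
    fit <- lm(Y ~ 1)
  } else {
    dat <- as.data.frame(X)
    fit <- lm(Y ~ ., data = dat)
    if (any(is.na(coef(fit)))) {
      warnf("rank-deficient design: %d aliased coefficient rows dropped",
            sum(apply(is.na(coef(fit)), 1, any)))
    }
  }
  R <- as.matrix(resid(fit))
  rank <- fit$rank
  list(fit = fit, ssr = sum(R^2), df_res = nrow(R) - rank,
       p = rank * ncol(R), rank = rank, residuals = R, n = nrow(R))
}

#' BIC of a multivariate linear fit, as printed
#'
#' Computes \eqn{-2 \log lik(\beta) + n \log p} with n the number of
#' multivariate observations and p the number of mean parameters; the
#' log-likelihood is the multivariate normal at the maximum-likelihood
#' residual covariance (divide-by-n). This penalty is implemented exactly as
#' the analysis it reproduces prints it; note it differs from the textbook
#' \eqn{p \log n}, which is available via `form = "plogn"`.
#'
#' @param fit a fit component from [manova_r2()] (or any list with
#'   `residuals`, `n`, `p`).
#' @param form `"nlogp"` (printed form, default) or `"plogn"`.
#' @param ridge relative ridge added to a singular residual covariance.
#' @return The BIC value (scalar).
#' @export
manova_bic <- function(fit, form = c("nlogp", "plogn"), ridge = 1e-8) {
  form <- match.arg(form)
  R <- as.matrix(fit$residuals)
  n <- fit$n
  q <- ncol(R)
  S <- crossprod(R) / n
  ld <- tryCatch(determinant(S, logarithm = TRUE),
                 error = function(e) NULL)
  if (is.null(ld) || ld$sign <= 0 ||
      !is.finite(ld$modulus)) {
    warnf("singular residual covariance; ridge-regularizing")
    S <- S + diag(ridge * sum(diag(S)) / q, q)
    ld <- determinant(S, logarithm = TRUE)
  }
  loglik <- -n / 2 * (q * log(2 * pi) + as.numeric(ld$modulus) + q)
  if (form == "nlogp") -2 * loglik + n * log(fit$p) else
    -2 * loglik + fit$p * log(n)
}
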