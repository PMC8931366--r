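#' Prevalence filter for count tables
#'
#' Keeps features observed (nonzero) in at least `min_prevalence` of samples,
#' preserving feature order. The state-typing default of 0.05 retains features
#' present in at least 5% of samples; `min_prevalence = 0` disables the filter.
#'
#' @param counts samples x features numeric matrix.
#' @param min_prevalence proportion in `[0, 1)`.
#' @return The filtered matrix.
#' @export
filter_prevalence <- function(counts, min_prevalence = 0.05) {
  counts <- as.matrix(counts)
  if (min_prevalence < 0 || min_prevalence >= 1) {
    stopf("min_prevalence must be in [0, 1)")
  }
  if (min_prevalence == 0) return(counts)
  prev <- colMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) {
    stopf("no features present in >= %.1f%% of samples", 100 * min_prevalence)
  }
  counts[, keep, drop = FALSE]
}

#' Depth-normalized integer counts from relative abundances
#'
#' Converts compositions to comparable count libraries by multiplying each
#' relative abundance by a fixed depth constant and rounding down, so that no
#' library exceeds the constant. The constants used for state typing mirror
#' minimum-read QC cutoffs (2250 rectal, 1200 nasal) and 50,000 for immune
#' population compositions; modeling raw library sizes is avoided because
#' high-count libraries otherwise dominate the mixture fit.
#'
#' @param relabund samples x features matrix of proportions (rows sum to ~1;
#'   raw counts are accepted and converted to proportions row-wise).
#' @param depth_constant positive integer scaling depth.
#' @return Integer matrix of class-compatible normalized counts, with
#'   attribute `depth_constant`.
#' @export
normalize_counts <- function(relabund, depth_constant) {
  m <- as.matrix(relabund)
  if (any(m < 0)) stopf("negative proportions are not allowed")
  if (depth_constant < 1) stopf("depth_constant must be >= 1")
  rs <- rowSums(m)
  if (any(rs == 0)) stopf("rows with zero total cannot be normalized")
  if (any(abs(rs - 1) > 1e-6)) m <- m / rs
  out <- floor(m * depth_constant)
  storage.mode(out) <- "integer"
  attr(out, "depth_constant") <- as.integer(depth_constant)
  out
}
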