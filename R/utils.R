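#' @keywords internal
"_PACKAGE"

# NAMESPACE is maintained by hand (S3 registrations, stats/utils imports,
# useDynLib); keep it in step when adding exports.

# Derive a 31-bit substream seed from a master seed and an index.
# Multiplicative hashing in double precision (exact below 2^53), reduced
# modulo a Mersenne prime so adding subjects never perturbs earlier ones.
substream_seed <- function(seed, index) {
  h <- (as.numeric(seed) %% 2147483647) + 0
  h <- (h * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647
  as.integer(h)
}

# FNV-1a hash of a serialized R object, reported as 8 hex digits.
# Used to stamp outputs with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Evaluate `expr` with a local RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Dirichlet sampler via gamma normalization.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

# z-score columns; zero-variance columns map to 0 rather than NaN.
zscore_cols <- function(m, center = NULL, scale = NULL) {
  m <- as.matrix(m)
  if (is.null(center)) center <- colMeans(m, na.rm = TRUE)
  if (is.null(scale)) scale <- apply(m, 2, sd, na.rm = TRUE)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  out <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}
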