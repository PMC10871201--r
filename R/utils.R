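# Internal helpers shared across modules.

#' Derive reproducible child seeds from a single run seed
#'
#' A single user-facing seed is expanded into independent per-stage seeds so
#' that pipeline stages (effect simulation, standard-error resampling, noise
#' injection, ...) are individually reproducible. The derivation seeds R's RNG
#' with the parent seed and draws `n` integers uniformly from
#' `1 .. .Machine$integer.max`.
#'
#' @param seed Integer parent seed, or `NULL` for no seeding.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, or `NULL` if `seed` is `NULL`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

# set.seed() unless seed is NULL
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Vectorized bivariate normal log density at points (x1, x2) with mean zero
# and per-point covariance [[a, b], [b, c]] (a, c may be vectors, b scalar or
# vector). Used for mixture likelihoods where each variant carries its own
# error covariance.
bvn_logdens <- function(x1, x2, a, b, c) {
  det <- a * c - b^2
  if (any(det <= 0)) stop("non-positive-definite 2x2 covariance")
  quad <- (c * x1^2 - 2 * b * x1 * x2 + a * x2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * quad
}

# Draw n points from a zero-mean bivariate normal with covariance `cov`,
# returned as an n x 2 matrix. Uses the Cholesky-like closed form for 2x2 so
# degenerate (perfectly correlated) covariances are handled exactly.
rbvn <- function(n, mean = c(0, 0), cov) {
  a <- cov[1, 1]; b <- cov[1, 2]; c <- cov[2, 2]
  stopifnot(a >= 0, c >= 0, abs(b) <= sqrt(a * c) + 1e-12)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  l11 <- sqrt(a)
  l21 <- if (l11 > 0) b / l11 else 0
  l22 <- sqrt(max(c - l21^2, 0))
  cbind(mean[1] + l11 * z1, mean[2] + l21 * z1 + l22 * z2)
}

# Coerce a two-column object (matrix or data.frame) to a numeric matrix.
as_two_col_matrix <- function(x, arg = deparse(substitute(x))) {
  m <- as.matrix(x)
  if (ncol(m) != 2L) stop(sprintf("`%s` must have exactly 2 columns", arg))
  storage.mode(m) <- "double"
  m
}
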