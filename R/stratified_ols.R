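#' Two-context genotype/trait sample
#'
#' Bundles genotypes and continuous trait values measured in two labelled
#' contexts (e.g. two environments, sexes, or diets). Genotypes are reference
#' allele counts in \{0, 1, 2\} at a single biallelic variant.
#'
#' @param genotypes_A,genotypes_B Integer vectors of allele counts in
#'   \{0, 1, 2\}.
#' @param traits_A,traits_B Numeric trait vectors, same lengths as the
#'   corresponding genotype vectors.
#' @return An object of class `"stratified_sample"`: a list with elements
#'   `genotypes_A`, `traits_A`, `genotypes_B`, `traits_B`, `n` (context-A
#'   sample size) and `m` (context-B sample size).
#' @examples
#' s <- stratified_sample(c(0, 1, 2, 1), c(0.1, 1.1, 2.2, 0.9),
#'                        c(1, 0, 2, 1), c(0.8, 0.2, 1.9, 1.1))
#' fit_stratified(s)
#' @export
stratified_sample <- function(genotypes_A, traits_A, genotypes_B, traits_B) {
  check_genotypes(genotypes_A)
  check_genotypes(genotypes_B)
  if (length(genotypes_A) != length(traits_A))
    stop("context A: genotype and trait lengths differ")
  if (length(genotypes_B) != length(traits_B))
    stop("context B: genotype and trait lengths differ")
  structure(
    list(genotypes_A = as.numeric(genotypes_A), traits_A = as.numeric(traits_A),
         genotypes_B = as.numeric(genotypes_B), traits_B = as.numeric(traits_B),
         n = length(genotypes_A), m = length(genotypes_B)),
    class = "stratified_sample")
}

check_genotypes <- function(g) {
  if (length(g) == 0L) stop("genotype vector is empty")
  if (anyNA(g) || !all(g %in% c(0, 1, 2)))
    stop("genotypes must be allele counts in {0, 1, 2}")
  invisible(g)
}

#' @export
print.stratified_sample <- function(x, ...) {
  cat(sprintf("Two-context sample: n = %d (A), m = %d (B)\n", x$n, x$m))
  cat(sprintf("  allele frequency A: %.4f  B: %.4f\n",
              mean(x$genotypes_A) / 2, mean(x$genotypes_B) / 2))
  invisible(x)
}

#' Simple ordinary least squares allelic-effect fit
#'
#' Regresses a continuous trait on allele count at one variant. Returns the
#' slope (the allelic effect), intercept, the residual variance estimate
#' (denominator n - 2), and the sampling variance of the slope
#' V = sigma^2 / sum((g - gbar)^2).
#'
#' @param g Genotype vector (allele counts in \{0, 1, 2\}).
#' @param y Trait vector, same length.
#' @return An object of class `"ols_fit"`: list with `beta_hat`,
#'   `intercept_hat`, `sampling_var`, `resid_var_hat`, `ss_g` (genotype sum of
#'   squares about its mean) and `n_obs`.
#' @examples
#' ols_simple(c(0, 1, 2, 1), c(0, 2, 4, 2))  # exact slope 2
#' @export
ols_simple <- function(g, y) {
  check_genotypes(g)
  g <- as.numeric(g); y <- as.numeric(y)
  n <- length(g)
  if (length(y) != n) stop("genotype and trait lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  gbar <- mean(g)
  ss_g <- sum((g - gbar)^2)
  if (ss_g <= 0) stop("degenerate input: constant genotypes")
  sxy <- sum((g - gbar) * (y - mean(y)))
  beta <- sxy / ss_g
  intercept <- mean(y) - beta * gbar
  rss <- sum((y - intercept - beta * g)^2)
  resid_var <- rss / (n - 2)
  structure(
    list(beta_hat = beta, intercept_hat = intercept,
         sampling_var = resid_var / ss_g, resid_var_hat = resid_var,
         ss_g = ss_g, n_obs = n),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS allelic-effect fit (n = %d)\n", x$n_obs))
  cat(sprintf("  beta_hat = %.6g (se %.6g), intercept = %.6g\n",
              x$beta_hat, sqrt(x$sampling_var), x$intercept_hat))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c(intercept = object$intercept_hat, beta = object$beta_hat)
}

#' Context-specific (GxE) estimation: one OLS fit per context
#'
#' Stratifies the sample by context and fits [ols_simple()] separately in
#' each, giving unbiased context-specific allelic-effect estimates. This is
#' equivalent to fitting a single linear model with a genotype-by-context
#' interaction term.
#'
#' @param s A [stratified_sample()].
#' @return List with elements `A` and `B`, each an `"ols_fit"`.
#' @export
fit_stratified <- function(s) {
  stopifnot(inherits(s, "stratified_sample"))
  list(A = ols_simple(s$genotypes_A, s$traits_A),
       B = ols_simple(s$genotypes_B, s$traits_B))
}

#' Additive (pooled) estimation: one OLS fit on the combined sample
#'
#' Fits a single regression to the concatenated sample, ignoring context.
#' The resulting slope is the additive allelic-effect estimator; it is
#' generally biased for either context-specific effect, but has lower
#' sampling variance than the stratified estimators.
#'
#' With `center_within_context = TRUE`, traits are mean-centered within each
#' context before pooling. Under within-context centering the pooled slope is
#' exactly the weighted combination `omega_A * beta_hat_A + omega_B *
#' beta_hat_B` of the stratified slopes, with weights given by
#' [combination_weights()]. Centering is off by default, matching ordinary
#' GWAS practice on raw traits.
#'
#' @param s A [stratified_sample()].
#' @param center_within_context Logical; mean-center traits per context
#'   before pooling.
#' @return An `"ols_fit"` for the pooled sample.
#' @export
fit_pooled <- function(s, center_within_context = FALSE) {
  stopifnot(inherits(s, "stratified_sample"))
  g <- c(s$genotypes_A, s$genotypes_B)
  y <- if (center_within_context) {
    c(s$traits_A - mean(s$traits_A), s$traits_B - mean(s$traits_B))
  } else {
    c(s$traits_A, s$traits_B)
  }
  ols_simple(g, y)
}
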