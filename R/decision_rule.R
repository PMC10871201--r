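#' Combination weights of the pooled estimator
#'
#' The pooled (additive) OLS slope is an exact linear combination of the two
#' stratified slopes, `beta_pooled = omega_A * beta_A_hat + omega_B *
#' beta_B_hat` (after within-context trait centering), with weights equal to
#' each context's genotype sum of squares over the pooled sum of squares.
#' The weights are non-negative but need not sum to 1; they sum to 1 exactly
#' when the context genotype means coincide, in which case
#' `omega_A = n * H_A / (n * H_A + m * H_B)` where `H = 2 f (1 - f)` is the
#' sample heterozygosity.
#'
#' @param genotypes_A,genotypes_B Allele-count vectors in \{0, 1, 2\} for the
#'   two contexts.
#' @return An object of class `"combination_weights"`: list with `omega_A`,
#'   `omega_B`, `ss_A`, `ss_B`, `ss_pooled`, `het_A`, `het_B`.
#' @examples
#' combination_weights(c(0, 1, 2, 1), c(1, 0, 2, 1))  # symmetric: 0.5 / 0.5
#' @export
combination_weights <- function(genotypes_A, genotypes_B) {
  check_genotypes(genotypes_A)
  check_genotypes(genotypes_B)
  gA <- as.numeric(genotypes_A); gB <- as.numeric(genotypes_B)
  pooled <- c(gA, gB)
  ss_pooled <- sum((pooled - mean(pooled))^2)
  if (ss_pooled <= 0)
    stop("degenerate input: pooled genotypes are constant")
  ss_A <- sum((gA - mean(gA))^2)
  ss_B <- sum((gB - mean(gB))^2)
  fA <- mean(gA) / 2
  fB <- mean(gB) / 2
  structure(
    list(omega_A = ss_A / ss_pooled, omega_B = ss_B / ss_pooled,
         ss_A = ss_A, ss_B = ss_B, ss_pooled = ss_pooled,
         het_A = 2 * fA * (1 - fA), het_B = 2 * fB * (1 - fB)),
    class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat(sprintf("Pooled-estimator weights: omega_A = %.4f, omega_B = %.4f (sum %.4f)\n",
              x$omega_A, x$omega_B, x$omega_A + x$omega_B))
  invisible(x)
}

#' Approximate combination weights from sample sizes and heterozygosities
#'
#' For summary-statistics input without raw genotypes, the genotype sums of
#' squares are approximated by `n * H` (valid when context genotype means are
#' close), giving `omega_A = n * H_A / (n * H_A + m * H_B)` and
#' `omega_B = 1 - omega_A`.
#'
#' @param n_A,n_B Context sample sizes.
#' @param het_A,het_B Sample heterozygosities `2 f (1 - f)`.
#' @return A `"combination_weights"` object (with `ss_*` set to the `n * H`
#'   approximations).
#' @export
approx_weights <- function(n_A, n_B, het_A, het_B) {
  stopifnot(n_A >= 1, n_B >= 1, het_A >= 0, het_B >= 0)
  ss_A <- n_A * het_A
  ss_B <- n_B * het_B
  tot <- ss_A + ss_B
  if (tot <= 0) stop("degenerate input: both contexts monomorphic")
  structure(
    list(omega_A = ss_A / tot, omega_B = ss_B / tot,
         ss_A = ss_A, ss_B = ss_B, ss_pooled = tot,
         het_A = het_A, het_B = het_B),
    class = "combination_weights")
}

#' Inputs to the additive-vs-GxE decision rule
#'
#' Collects the quantities entering the mean-squared-error comparison for
#' estimating the allelic effect in the focal context A: the two true (or
#' estimated) context-specific effects, the sampling variances of the
#' stratified estimators, and the pooled-estimator combination weights.
#'
#' @param beta_A,beta_B Allelic effects in the focal and other context
#'   (trait units per allele).
#' @param var_A,var_B Sampling variances of the stratified estimators
#'   (squared trait units); non-negative.
#' @param weights A `"combination_weights"` object (or a list with `omega_A`
#'   and `omega_B`).
#' @param r Optional noise ratio `var_A / var_B`; when both variances are
#'   positive it must agree with their ratio.
#' @return An object of class `"decision_inputs"`.
#' @export
decision_inputs <- function(beta_A, beta_B, var_A, var_B, weights, r = NULL) {
  stopifnot(is.finite(beta_A), is.finite(beta_B),
            var_A >= 0, var_B >= 0,
            is.list(weights), !is.null(weights$omega_A), !is.null(weights$omega_B))
  if (!is.null(r)) {
    if (r <= 0) stop("r must be positive")
    if (var_A > 0 && var_B > 0 &&
        abs(r - var_A / var_B) > 1e-8 * max(1, r))
      stop("r inconsistent with var_A / var_B")
  }
  structure(
    list(beta_A = beta_A, beta_B = beta_B, var_A = var_A, var_B = var_B,
         weights = weights, r = r),
    class = "decision_inputs")
}

#' Mean squared error of the additive and GxE estimators
#'
#' For the focal context A, the stratified (GxE) estimator is unbiased with
#' MSE equal to its sampling variance `var_A`. The pooled (additive)
#' estimator trades bias for variance:
#' `MSE_additive = ((omega_A - 1) beta_A + omega_B beta_B)^2 +
#'  omega_A^2 var_A + omega_B^2 var_B`.
#'
#' @param d A [decision_inputs()].
#' @return Named numeric vector `c(mse_additive, mse_gxe)` in squared trait
#'   units.
#' @examples
#' w <- approx_weights(100, 100, 0.5, 0.5)
#' evaluate_mse(decision_inputs(1, 0, 0.1, 0.1, w))
#' @export
evaluate_mse <- function(d) {
  stopifnot(inherits(d, "decision_inputs"))
  wA <- d$weights$omega_A; wB <- d$weights$omega_B
  bias <- (wA - 1) * d$beta_A + wB * d$beta_B
  c(mse_additive = bias^2 + wA^2 * d$var_A + wB^2 * d$var_B,
    mse_gxe = d$var_A)
}

#' Decide between the additive and GxE estimators
#'
#' Prefers the context-specific (GxE) estimator exactly when the additive
#' estimator's MSE for the focal context exceeds the stratified estimator's
#' sampling variance.
#'
#' @param d A [decision_inputs()].
#' @param tol Absolute tolerance within which the two MSEs are declared tied.
#' @return `"GXE"`, `"ADDITIVE"`, or `"TIE"`.
#' @export
prefer_gxe <- function(d, tol = 0) {
  mse <- evaluate_mse(d)
  diff <- mse[["mse_additive"]] - mse[["mse_gxe"]]
  if (abs(diff) <= tol) "TIE" else if (diff > 0) "GXE" else "ADDITIVE"
}

#' Signal-to-noise form of the decision rule (equal heterozygosity)
#'
#' When heterozygosity is equal across contexts (so `omega_A + omega_B = 1`),
#' the decision rule reduces to a comparison of unitless quantities: prefer
#' GxE estimation iff
#' `(beta_A - beta_B)^2 / var_A > (1 + omega_A) / (1 - omega_A) -
#'  var_B / var_A`.
#' The left-hand side is the signal-to-noise ratio; the right-hand side
#' combines the relative heterozygosity contribution and the noise ratio.
#'
#' @param beta_A,beta_B Context-specific effects.
#' @param var_A,var_B Stratified-estimator sampling variances; `var_A > 0`.
#' @param omega_A Combination weight of context A, strictly in (0, 1).
#' @param tol Tie tolerance on the decision statistic.
#' @return `"GXE"`, `"ADDITIVE"`, or `"TIE"`.
#' @export
snr_decision <- function(beta_A, beta_B, var_A, var_B, omega_A, tol = 0) {
  if (omega_A <= 0 || omega_A >= 1) stop("omega_A must lie strictly in (0, 1)")
  stopifnot(var_A > 0, var_B >= 0)
  lhs <- (beta_A - beta_B)^2 / var_A
  rhs <- (1 + omega_A) / (1 - omega_A) - var_B / var_A
  diff <- lhs - rhs
  if (abs(diff) <= tol) "TIE" else if (diff > 0) "GXE" else "ADDITIVE"
}

#' Noise-ratio threshold below which the additive estimator is never preferred
#'
#' With equal heterozygosities, the right-hand side of the signal-to-noise
#' rule is negative whenever the noise ratio `r = var_A / var_B` falls below
#' `r_star = (1 - omega_A) / (1 + omega_A)`; since the signal-to-noise ratio
#' is non-negative, GxE estimation is then always preferred in the focal
#' context (e.g. `r_star = 1/3` at `omega_A = 1/2`).
#'
#' @param omega_A Combination weight in (0, 1).
#' @return `r_star`, unitless.
#' @export
never_additive_threshold <- function(omega_A) {
  if (any(omega_A <= 0 | omega_A >= 1))
    stop("omega_A must lie strictly in (0, 1)")
  (1 - omega_A) / (1 + omega_A)
}

#' Decision boundary in standard-deviation units (equal frequency, equal noise)
#'
#' Under equal allele frequencies and equal estimation noise in the two
#' contexts (`r = 1`, `omega_A = n / (n + m)`), the two estimators have equal
#' MSE along a line in the (|beta_A - beta_B|, estimator sd) plane:
#' `sd_star = sqrt(m / (2 n)) * |beta_A - beta_B|`. Points with estimator sd
#' below the boundary prefer GxE estimation.
#'
#' @param delta Absolute difference of context-specific effects, trait units.
#' @param n,m Context sample sizes.
#' @return `sd_star` in trait units.
#' @export
boundary_sd <- function(delta, n, m) {
  stopifnot(n >= 1, m >= 1, all(delta >= 0))
  sqrt(m / (2 * n)) * delta
}

#' Screen a two-context summary-statistics table with the decision rule
#'
#' Plugs per-variant estimated effects and standard errors into the MSE
#' decision rule to flag, for each variant, whether the focal context's
#' effect is expected to be more accurately estimated by the additive or by
#' the context-specific (GxE) estimator.
#'
#' The naive plug-in `(beta_hat_A - beta_hat_B)^2` overstates the true
#' squared effect difference by the two sampling variances; with
#' `bias_correct = TRUE` (default) it is replaced by the moment-corrected
#' `max(0, (beta_hat_A - beta_hat_B)^2 - V_A - V_B)`.
#'
#' @param sumstats Data frame as returned by [read_sumstats()]: columns
#'   `variant_id`, `beta_A`, `se_A`, `n_A`, `beta_B`, `se_B`, `n_B`, and
#'   optionally `af_A`, `af_B` (required to approximate weights).
#' @param focal `"A"` or `"B"`: the context whose effect is being estimated.
#' @param r_proxy Optional fixed noise ratio `V_focal / V_other` applied to
#'   every row (e.g. a ratio of context-specific trait variances); when
#'   supplied, the other context's variance is derived as `se_focal^2 /
#'   r_proxy` instead of from its own standard error.
#' @param bias_correct Logical; apply the moment correction to the squared
#'   effect difference.
#' @param tol Tie tolerance passed to the decision.
#' @return The input table with added columns `omega_A`, `mse_additive`,
#'   `mse_gxe`, `mse_diff` (additive minus GxE) and `decision`. Rows with
#'   missing or non-positive standard errors are dropped with a warning.
#' @export
decision_screen <- function(sumstats, focal = c("A", "B"), r_proxy = NULL,
                            bias_correct = TRUE, tol = 0) {
  focal <- match.arg(focal)
  req <- c("beta_A", "se_A", "n_A", "beta_B", "se_B", "n_B")
  missing_cols <- setdiff(req, names(sumstats))
  if (length(missing_cols))
    stop("sumstats is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  ok <- is.finite(sumstats$se_A) & sumstats$se_A > 0 &
    is.finite(sumstats$se_B) & sumstats$se_B > 0
  if (!all(ok)) {
    warning(sprintf("dropping %d row(s) with missing or non-positive standard errors",
                    sum(!ok)))
    sumstats <- sumstats[ok, , drop = FALSE]
  }
  if (!all(c("af_A", "af_B") %in% names(sumstats)))
    stop("allele-frequency columns af_A and af_B are required to approximate weights")

  het_A <- 2 * sumstats$af_A * (1 - sumstats$af_A)
  het_B <- 2 * sumstats$af_B * (1 - sumstats$af_B)
  ssA <- sumstats$n_A * het_A
  ssB <- sumstats$n_B * het_B
  omega_A <- ssA / (ssA + ssB)

  if (focal == "A") {
    bF <- sumstats$beta_A; bO <- sumstats$beta_B
    vF <- sumstats$se_A^2; vO <- sumstats$se_B^2
    wF <- omega_A; wO <- 1 - omega_A
  } else {
    bF <- sumstats$beta_B; bO <- sumstats$beta_A
    vF <- sumstats$se_B^2; vO <- sumstats$se_A^2
    wF <- 1 - omega_A; wO <- omega_A
  }
  if (!is.null(r_proxy)) {
    stopifnot(length(r_proxy) == 1L, r_proxy > 0)
    vO <- vF / r_proxy
  }

  diff2 <- (bF - bO)^2
  if (bias_correct) diff2 <- pmax(0, diff2 - vF - vO)
  # bias of the pooled estimator for the focal effect is (wF - 1) bF + wO bO
  # = wO (bO - bF); with the moment correction applied to (bF - bO)^2
  bias2 <- wO^2 * diff2
  mse_additive <- bias2 + wF^2 * vF + wO^2 * vO
  mse_gxe <- vF
  mse_diff <- mse_additive - mse_gxe
  decision <- ifelse(abs(mse_diff) <= tol, "TIE",
                     ifelse(mse_diff > 0, "GXE", "ADDITIVE"))
  out <- sumstats
  out$omega_A <- omega_A
  out$mse_additive <- mse_additive
  out$mse_gxe <- mse_gxe
  out$mse_diff <- mse_diff
  out$decision <- decision
  out
}
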