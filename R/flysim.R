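#' Configuration for the GxDiet amplification simulation
#'
#' Parameters of the pervasive-amplification generative model for allelic
#' effects on fly longevity under a control and a high-sugar diet. Non-null
#' effect pairs are drawn from a bivariate normal whose default covariance
#' implies perfectly correlated effects that are systematically 1.4x larger
#' under the high-sugar diet.
#'
#' `pi_null` has no default: published descriptions of the model state both a
#' 40% and a 60% null fraction, so the caller must choose (both presets are
#' exported as `flysim_presets`).
#'
#' @param pi_null Probability a variant has no effect under either diet.
#' @param p Number of variants.
#' @param mu Mean of non-null effect pairs `(control, high_sugar)`.
#' @param cov 2x2 covariance of non-null effect pairs.
#' @param q_thresh Per-diet q-value significance threshold.
#' @param p_thresh Per-diet p-value "clearly not significant" threshold used
#'   by the diet-specific classification rules.
#' @return Object of class `"flysim_config"`.
#' @export
flysim_config <- function(pi_null, p = 50000,
                          mu = c(-0.125, -0.15),
                          cov = 0.01 * matrix(c(1, 1.4, 1.4, 1.96), 2, 2),
                          q_thresh = 0.01, p_thresh = 0.1) {
  stopifnot(pi_null >= 0, pi_null <= 1, p >= 1,
            length(mu) == 2, all(dim(cov) == c(2, 2)),
            isTRUE(all.equal(cov[1, 2], cov[2, 1])),
            q_thresh > 0, q_thresh < 1, p_thresh > 0, p_thresh < 1)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("cov must be positive semi-definite")
  structure(list(pi_null = pi_null, p = as.integer(p), mu = mu, cov = cov,
                 q_thresh = q_thresh, p_thresh = p_thresh),
            class = "flysim_config")
}

#' Null-fraction presets for the GxDiet simulation
#'
#' Both described null fractions of the amplification model: `results_preset`
#' (40% null) and `methods_preset` (60% null).
#' @export
flysim_presets <- c(results_preset = 0.4, methods_preset = 0.6)

#' Simulate true diet-specific effect pairs
#'
#' With probability `pi_null` a variant's effect pair is exactly (0, 0);
#' otherwise it is drawn from the bivariate normal `N(mu, cov)` of the
#' configuration.
#'
#' @param cfg A [flysim_config()].
#' @param seed Optional seed.
#' @return Data frame with columns `true_c` (control) and `true_h`
#'   (high sugar).
#' @export
simulate_true_effects <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "flysim_config"))
  maybe_seed(seed)
  null <- stats::runif(cfg$p) < cfg$pi_null
  eff <- matrix(0, cfg$p, 2)
  n_eff <- sum(!null)
  if (n_eff > 0)
    eff[!null, ] <- rbvn(n_eff, mean = cfg$mu, cov = cfg$cov)
  data.frame(true_c = eff[, 1], true_h = eff[, 2])
}

#' Resample paired standard errors with replacement
#'
#' Draws `p` rows (variant indices) with replacement from a table of paired
#' per-variant standard errors, keeping each (control, high-sugar) pair
#' together since both come from the same source variant.
#'
#' @param se_table Data frame or matrix with two positive columns: control
#'   and high-sugar standard errors.
#' @param p Number of rows to draw.
#' @param seed Optional seed.
#' @return Data frame with columns `se_c`, `se_h` and `p` rows.
#' @export
resample_ses <- function(se_table, p, seed = NULL) {
  m <- as_two_col_matrix(se_table, "se_table")
  if (nrow(m) < 1L) stop("se_table must have at least one row")
  if (any(m <= 0)) stop("standard errors must be positive")
  maybe_seed(seed)
  idx <- sample.int(nrow(m), p, replace = TRUE)
  data.frame(se_c = m[idx, 1], se_h = m[idx, 2])
}

#' Add estimation noise to true effects
#'
#' Each estimate is drawn independently (across variants and diets) from a
#' normal centered at the true effect with sd equal to the variant's
#' assigned standard error.
#'
#' @param true_effects Two-column table of true effects (control, high sugar).
#' @param ses Two-column table of matching positive standard errors.
#' @param seed Optional seed.
#' @return Data frame with columns `est_c`, `est_h`.
#' @export
add_estimation_noise <- function(true_effects, ses, seed = NULL) {
  b <- as_two_col_matrix(true_effects, "true_effects")
  s <- as_two_col_matrix(ses, "ses")
  if (nrow(b) != nrow(s)) stop("true_effects and ses must have matching rows")
  if (any(s <= 0)) stop("standard errors must be positive")
  maybe_seed(seed)
  data.frame(est_c = stats::rnorm(nrow(b), b[, 1], s[, 1]),
             est_h = stats::rnorm(nrow(b), b[, 2], s[, 2]))
}

#' Two-sided Z-test p-values
#'
#' @param estimates Numeric vector (or matrix) of effect estimates.
#' @param ses Matching positive standard errors.
#' @return Two-sided normal-tail p-values, same shape as `estimates`.
#' @export
ztest_pvalues <- function(estimates, ses) {
  if (any(ses <= 0)) stop("standard errors must be positive")
  p <- 2 * stats::pnorm(-abs(estimates / ses))
  pmax(p, .Machine$double.xmin)
}

#' q-values (Storey or Benjamini-Hochberg)
#'
#' Storey q-values estimate the null proportion as
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` and multiply the
#' Benjamini-Hochberg step-up adjusted p-values by `pi0`; with `method =
#' "bh"` (equivalently `pi0 = 1`) they reduce to BH adjusted p-values.
#'
#' @param pvec p-values in (0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Tuning point for the Storey null-proportion estimate.
#' @return q-values, monotone in `pvec`.
#' @export
qvalues <- function(pvec, method = c("storey", "bh"), lambda = 0.5) {
  method <- match.arg(method)
  stopifnot(all(pvec > 0), all(pvec <= 1))
  q_bh <- stats::p.adjust(pvec, method = "BH")
  if (method == "bh") return(q_bh)
  stopifnot(lambda > 0, lambda < 1)
  pi0 <- min(1, mean(pvec > lambda) / (1 - lambda))
  pmin(pi0 * q_bh, 1)
}

#' Classify variants by per-diet significance
#'
#' The four-category "top hits" classification: a variant significant (q
#' below `q_thresh`) in both diets is `shared`; significant in one diet and
#' clearly non-significant (p at or above `p_thresh`) in the other is
#' diet-specific; non-significant in both is `no_effect`. Combinations the
#' four published rules do not cover (significant in one diet with the other
#' diet's p-value between significance and `p_thresh`) are labelled
#' `unclassified`. Precedence: shared, then diet-specific, then no-effect.
#'
#' @param p_c,p_h Per-diet p-values (control, high sugar).
#' @param q_c,q_h Per-diet q-values.
#' @param q_thresh,p_thresh Classification thresholds.
#' @return Factor with levels `no_effect`, `control_specific`,
#'   `high_sugar_specific`, `shared`, `unclassified`.
#' @export
classify_variants <- function(p_c, p_h, q_c, q_h,
                              q_thresh = 0.01, p_thresh = 0.1) {
  n <- length(p_c)
  stopifnot(length(p_h) == n, length(q_c) == n, length(q_h) == n)
  lab <- rep("unclassified", n)
  lab[q_h < q_thresh & q_c < q_thresh] <- "shared"
  lab[q_h < q_thresh & q_c >= q_thresh & p_c >= p_thresh] <- "high_sugar_specific"
  lab[q_c < q_thresh & q_h >= q_thresh & p_h >= p_thresh] <- "control_specific"
  lab[q_h >= q_thresh & q_c >= q_thresh] <- "no_effect"
  factor(lab, levels = c("no_effect", "control_specific",
                         "high_sugar_specific", "shared", "unclassified"))
}

#' Tabulate the top-hits classification
#'
#' @param labels Factor from [classify_variants()].
#' @return List with `counts` and `fractions` over all variants, and
#'   `significant_fractions`: the composition of the significant classes
#'   (`control_specific`, `high_sugar_specific`, `shared`) among themselves;
#'   empty (all counts zero) when no variant is significant.
#' @export
summarize_classification <- function(labels) {
  labels <- factor(labels, levels = c("no_effect", "control_specific",
                                      "high_sugar_specific", "shared",
                                      "unclassified"))
  counts <- table(labels)
  sig_classes <- c("control_specific", "high_sugar_specific", "shared")
  sig_counts <- counts[sig_classes]
  n_sig <- sum(sig_counts)
  sig_frac <- if (n_sig > 0) sig_counts / n_sig else sig_counts * 0
  list(counts = counts,
       fractions = counts / sum(counts),
       n_significant = n_sig,
       significant_fractions = sig_frac)
}

#' Run the full GxDiet amplification pipeline
#'
#' Simulates true effect pairs, assigns paired standard errors (resampled
#' from `se_table`, or from [synthetic_se_fixture()] when none is given),
#' adds estimation noise, computes per-diet Z-test p-values and q-values,
#' and classifies every variant.
#'
#' @param cfg A [flysim_config()].
#' @param se_table Optional two-column table of paired standard errors
#'   (control, high sugar); defaults to a synthetic log-normal fixture.
#' @param seed Optional seed; expanded into independent per-stage seeds.
#' @param qvalue_method Passed to [qvalues()].
#' @return Data frame (one row per variant) with columns `true_c`, `true_h`,
#'   `est_c`, `est_h`, `se_c`, `se_h`, `p_c`, `p_h`, `q_c`, `q_h`, `label`,
#'   with the configuration attached as attribute `"config"`.
#' @export
run_flysim <- function(cfg, se_table = NULL, seed = NULL,
                       qvalue_method = c("storey", "bh")) {
  stopifnot(inherits(cfg, "flysim_config"))
  qvalue_method <- match.arg(qvalue_method)
  seeds <- derive_seeds(seed, 4)
  sd_at <- function(i) if (is.null(seeds)) NULL else seeds[i]
  if (is.null(se_table))
    se_table <- synthetic_se_fixture(p = 5000, seed = sd_at(4))
  truth <- simulate_true_effects(cfg, seed = sd_at(1))
  ses <- resample_ses(se_table, cfg$p, seed = sd_at(2))
  est <- add_estimation_noise(truth, ses, seed = sd_at(3))
  p_c <- ztest_pvalues(est$est_c, ses$se_c)
  p_h <- ztest_pvalues(est$est_h, ses$se_h)
  q_c <- qvalues(p_c, method = qvalue_method)
  q_h <- qvalues(p_h, method = qvalue_method)
  label <- classify_variants(p_c, p_h, q_c, q_h, cfg$q_thresh, cfg$p_thresh)
  out <- data.frame(truth, est, ses, p_c = p_c, p_h = p_h,
                    q_c = q_c, q_h = q_h, label = label)
  attr(out, "config") <- cfg
  out
}
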