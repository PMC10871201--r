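#' Configuration for the two-context polygenic-score simulation
#'
#' Parameters of the simulation comparing polygenic-scoring strategies in
#' two contexts under pervasive amplification. Per variant, minor allele
#' frequencies are `Beta(s1, s2) / 2` and genotypes `Binomial(2, f)`. True
#' effect pairs come from the mixture
#' `pi0 * delta_0 + (1 - pi0) * (alpha * N(0, eq_cov) + (1 - alpha) *
#'  N(0, amp_cov))`:
#' a null point mass, an equal-effects component, and an amplified component
#' whose default covariance `[[3/2, 1], [1, 2/3]]` gives perfectly correlated
#' effects with 1.5x the standard deviation in context A. Residual variance
#' is calibrated per context so the realized narrow-sense heritability of the
#' training cohort equals `h2`.
#'
#' @param n_train Training-cohort size per context.
#' @param alpha Fraction of non-null variants with exactly equal effects.
#' @param n_test Test-cohort size per context.
#' @param p Number of variants.
#' @param pi0 Null fraction.
#' @param eq_cov,amp_cov 2x2 covariances of the two non-null components.
#' @param s1,s2 Beta parameters of the allele-frequency distribution.
#' @param h2 Per-context narrow-sense heritability in (0, 1].
#' @param k_ascertain Number of variants included in each score.
#' @return Object of class `"pgs_config"`.
#' @export
pgs_config <- function(n_train = 1000, alpha = 0.5, n_test = 3000, p = 5000,
                       pi0 = 0.5,
                       eq_cov = matrix(1, 2, 2),
                       amp_cov = matrix(c(3 / 2, 1, 1, 2 / 3), 2, 2),
                       s1 = 1, s2 = 5, h2 = 0.4, k_ascertain = 833) {
  stopifnot(n_train >= 10, n_test >= 10, p >= 2,
            pi0 >= 0, pi0 <= 1, alpha >= 0, alpha <= 1,
            s1 > 0, s2 > 0, h2 > 0, h2 <= 1,
            k_ascertain >= 1, k_ascertain <= p,
            all(dim(eq_cov) == c(2, 2)), all(dim(amp_cov) == c(2, 2)))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 p = as.integer(p), pi0 = pi0, alpha = alpha,
                 eq_cov = eq_cov, amp_cov = amp_cov, s1 = s1, s2 = s2,
                 h2 = h2, k_ascertain = as.integer(k_ascertain)),
            class = "pgs_config")
}

#' Simulate a genotype matrix with Beta-distributed allele frequencies
#'
#' @param n Individuals. @param p Variants.
#' @param s1,s2 Beta shape parameters; allele frequencies are
#'   `Beta(s1, s2) / 2`.
#' @param seed Optional seed.
#' @param freqs Optional fixed per-variant frequencies (length `p`); when
#'   supplied, `s1`/`s2` are ignored (used to draw several cohorts from one
#'   population).
#' @return List with `G` (n x p integer matrix of allele counts) and `freqs`.
#' @export
simulate_genotypes <- function(n, p, s1 = 1, s2 = 5, seed = NULL, freqs = NULL) {
  stopifnot(n >= 1, p >= 1)
  maybe_seed(seed)
  if (is.null(freqs)) freqs <- stats::rbeta(p, s1, s2) / 2
  stopifnot(length(freqs) == p, all(freqs >= 0), all(freqs <= 1))
  G <- matrix(stats::rbinom(n * p, 2L, rep(freqs, each = n)), nrow = n, ncol = p)
  list(G = G, freqs = freqs)
}

#' Simulate true effect pairs from the null/equal/amplified mixture
#'
#' @param p Number of variants.
#' @param pi0 Null fraction.
#' @param alpha Equal-effects fraction among non-null variants.
#' @param eq_cov,amp_cov Component covariances.
#' @param seed Optional seed.
#' @return `p x 2` matrix of effects (columns: contexts A, B) with attribute
#'   `"component"` in \{"null", "equal", "amplified"\}.
#' @export
simulate_effect_pairs <- function(p, pi0 = 0.5, alpha = 0.5,
                                  eq_cov = matrix(1, 2, 2),
                                  amp_cov = matrix(c(3 / 2, 1, 1, 2 / 3), 2, 2),
                                  seed = NULL) {
  stopifnot(p >= 1, pi0 >= 0, pi0 <= 1, alpha >= 0, alpha <= 1)
  maybe_seed(seed)
  u <- stats::runif(p)
  comp <- ifelse(u < pi0, "null",
                 ifelse(u < pi0 + (1 - pi0) * alpha, "equal", "amplified"))
  eff <- matrix(0, p, 2)
  if (any(comp == "equal"))
    eff[comp == "equal", ] <- rbvn(sum(comp == "equal"), cov = eq_cov)
  if (any(comp == "amplified"))
    eff[comp == "amplified", ] <- rbvn(sum(comp == "amplified"), cov = amp_cov)
  attr(eff, "component") <- comp
  eff
}

#' Simulate phenotypes at a target heritability
#'
#' Residual variance is set from the empirical genetic variance of the
#' supplied cohort, `sigma2 = var(G beta) * (1 - h2) / h2`, so the realized
#' heritability of the generating cohort matches `h2`; `sigma2` may instead
#' be supplied directly (e.g. to reuse the training calibration for a test
#' cohort).
#'
#' @param G Genotype matrix. @param effects Effect vector (length `ncol(G)`).
#' @param h2 Target heritability in (0, 1].
#' @param seed Optional seed.
#' @param sigma2 Optional residual variance overriding the calibration.
#' @return List with `y`, `genetic` (the vector `G beta`) and `sigma2`.
#' @export
simulate_phenotypes <- function(G, effects, h2 = 0.4, seed = NULL, sigma2 = NULL) {
  stopifnot(h2 > 0, h2 <= 1, ncol(G) == length(effects))
  genetic <- as.vector(G %*% effects)
  if (is.null(sigma2)) {
    vg <- stats::var(genetic)
    if (vg == 0 && h2 < 1)
      stop("Var(G beta) is zero: no genetic signal to scale against")
    sigma2 <- vg * (1 - h2) / h2
  }
  maybe_seed(seed)
  y <- genetic + stats::rnorm(length(genetic), 0, sqrt(sigma2))
  list(y = y, genetic = genetic, sigma2 = sigma2)
}

#' Marginal per-variant GWAS scan
#'
#' Independent simple OLS regressions of the trait on each variant's allele
#' count, with two-sided normal-approximation p-values. Monomorphic variants
#' are flagged (`NA` estimates) and skipped downstream.
#'
#' @param G Genotype matrix (individuals x variants).
#' @param y Trait vector.
#' @return Data frame with `beta`, `se`, `z`, `pvalue`, `monomorphic`.
#' @export
gwas_scan <- function(G, y) {
  n <- length(y)
  stopifnot(nrow(G) == n, n >= 3)
  gbar <- colMeans(G)
  sxx <- colSums(G^2) - n * gbar^2
  mono <- sxx < 1e-10
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(G, yc))
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  syy <- sum(yc^2)
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  se[mono] <- NA_real_
  z <- beta / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  data.frame(beta = beta, se = se, z = z, pvalue = pvalue, monomorphic = mono)
}

#' Ascertain the top-k most significant variants
#'
#' Returns the indices of the `k` smallest p-values; ties are broken by
#' larger absolute z-score, then by lower index. `NA` p-values (monomorphic
#' variants) sort last.
#'
#' @param pvalues Per-variant p-values.
#' @param k Number of variants to select.
#' @param z Optional z-scores for tie-breaking.
#' @return Integer index vector of length `k`.
#' @export
ascertain_top_k <- function(pvalues, k, z = NULL) {
  stopifnot(k >= 1, k <= length(pvalues))
  pv <- ifelse(is.na(pvalues), Inf, pvalues)
  tie <- if (is.null(z)) rep(0, length(pv)) else -abs(ifelse(is.na(z), 0, z))
  ord <- order(pv, tie, seq_along(pv))
  ord[seq_len(k)]
}

#' Score a test cohort and evaluate prediction accuracy
#'
#' Polygenic score = sum over selected variants of weight times allele
#' count; accuracy is the Pearson correlation with the test trait. A
#' zero-variance score (or trait) yields correlation 0 with a warning.
#'
#' @param G_test Test genotype matrix. @param y_test Test trait vector.
#' @param index_set Variant indices included in the score.
#' @param weights Per-variant weights aligned with `index_set`.
#' @return Pearson correlation (scalar).
#' @export
build_and_evaluate_score <- function(G_test, y_test, index_set, weights) {
  stopifnot(length(index_set) == length(weights))
  w <- ifelse(is.na(weights), 0, weights)
  score <- as.vector(G_test[, index_set, drop = FALSE] %*% w)
  if (stats::sd(score) == 0 || stats::sd(y_test) == 0) {
    warning("zero-variance polygenic score; reporting correlation 0")
    return(0)
  }
  stats::cor(score, y_test)
}

# One simulation replicate: returns a long data.frame of per-strategy,
# per-context out-of-sample correlations.
run_pgs_rep <- function(cfg, seed = NULL, shrink_prior = NULL,
                        shrink_ascertain = c("pvalue", "pseudo_p")) {
  shrink_ascertain <- match.arg(shrink_ascertain)
  seeds <- derive_seeds(seed, 10)
  sd_at <- function(i) if (is.null(seeds)) NULL else seeds[i]

  eff <- simulate_effect_pairs(cfg$p, cfg$pi0, cfg$alpha, cfg$eq_cov,
                               cfg$amp_cov, seed = sd_at(1))
  maybe_seed(sd_at(2))
  freqs <- stats::rbeta(cfg$p, cfg$s1, cfg$s2) / 2
  trA <- simulate_genotypes(cfg$n_train, cfg$p, freqs = freqs, seed = sd_at(3))
  trB <- simulate_genotypes(cfg$n_train, cfg$p, freqs = freqs, seed = sd_at(4))
  teA <- simulate_genotypes(cfg$n_test, cfg$p, freqs = freqs, seed = sd_at(5))
  teB <- simulate_genotypes(cfg$n_test, cfg$p, freqs = freqs, seed = sd_at(6))

  phA <- simulate_phenotypes(trA$G, eff[, 1], cfg$h2, seed = sd_at(7))
  phB <- simulate_phenotypes(trB$G, eff[, 2], cfg$h2, seed = sd_at(8))
  yA_test <- simulate_phenotypes(teA$G, eff[, 1], cfg$h2, seed = sd_at(9),
                                 sigma2 = phA$sigma2)$y
  yB_test <- simulate_phenotypes(teB$G, eff[, 2], cfg$h2, seed = sd_at(10),
                                 sigma2 = phB$sigma2)$y

  scanA <- gwas_scan(trA$G, phA$y)
  scanB <- gwas_scan(trB$G, phB$y)
  scan_pool <- gwas_scan(rbind(trA$G, trB$G), c(phA$y, phB$y))

  ok <- !(scanA$monomorphic | scanB$monomorphic)
  bhat <- cbind(scanA$beta, scanB$beta)[ok, , drop = FALSE]
  shat <- cbind(scanA$se, scanB$se)[ok, , drop = FALSE]
  if (is.null(shrink_prior)) shrink_prior <- prior_grid(auto_scales(bhat, shat))
  fit <- gxe_shrink(bhat, shat, prior = shrink_prior)
  post <- matrix(NA_real_, cfg$p, 2)
  ppse <- matrix(NA_real_, cfg$p, 2)
  post[ok, ] <- as.matrix(fit$posterior[, c("post_mean_A", "post_mean_B")])
  ppse[ok, ] <- as.matrix(fit$posterior[, c("pseudo_p_A", "pseudo_p_B")])

  k <- cfg$k_ascertain
  idx_add <- ascertain_top_k(scan_pool$pvalue, k, scan_pool$z)
  idx_ctx <- list(A = ascertain_top_k(scanA$pvalue, k, scanA$z),
                  B = ascertain_top_k(scanB$pvalue, k, scanB$z))
  idx_shr <- if (shrink_ascertain == "pvalue") idx_ctx else
    list(A = ascertain_top_k(ppse[, 1], k),
         B = ascertain_top_k(ppse[, 2], k))

  ctx_scan <- list(A = scanA, B = scanB)
  ctx_test <- list(A = list(G = teA$G, y = yA_test),
                   B = list(G = teB$G, y = yB_test))
  rows <- list()
  for (ctx in c("A", "B")) {
    ci <- if (ctx == "A") 1L else 2L
    te <- ctx_test[[ctx]]
    r <- c(
      additive_ascert_additive_est =
        build_and_evaluate_score(te$G, te$y, idx_add, scan_pool$beta[idx_add]),
      additive_ascert_gxe_est =
        build_and_evaluate_score(te$G, te$y, idx_add, ctx_scan[[ctx]]$beta[idx_add]),
      gxe_ascert_gxe_est =
        build_and_evaluate_score(te$G, te$y, idx_ctx[[ctx]],
                                 ctx_scan[[ctx]]$beta[idx_ctx[[ctx]]]),
      gxe_ascert_mash_est =
        build_and_evaluate_score(te$G, te$y, idx_shr[[ctx]],
                                 post[idx_shr[[ctx]], ci]))
    rows[[ctx]] <- data.frame(strategy = names(r), context = ctx,
                              pearson_r = unname(r))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the polygenic-score strategy comparison
#'
#' For each value of `alpha` (the equal-effects fraction) and each
#' replicate: simulate training and test cohorts in two contexts, run
#' pooled and per-context GWAS scans, fit the empirical-Bayes shrinkage
#' model on the per-context estimates, build four polygenic scores
#' (additive ascertainment + additive weights; additive ascertainment +
#' context-specific weights; context-specific ascertainment + weights;
#' context-specific ascertainment + posterior-mean weights), and record each
#' score's out-of-sample Pearson correlation in each context.
#'
#' @param cfg A [pgs_config()].
#' @param alpha_grid Values of the equal-effects fraction to sweep.
#' @param n_reps Replicates per alpha.
#' @param seed Optional seed (expanded per replicate).
#' @param shrink_prior Optional fixed [prior_grid()] for the shrinkage fit
#'   (default: data-driven per replicate).
#' @param shrink_ascertain `"pvalue"` (context-specific test p-values,
#'   default) or `"pseudo_p"` (posterior pseudo p-values) for the shrinkage
#'   strategy's variant selection.
#' @return Long data frame: `alpha`, `rep`, `strategy`, `context`,
#'   `pearson_r`, of class `c("pgs_grid", "data.frame")`.
#' @seealso [summarize_strategy_grid()]
#' @export
run_strategy_grid <- function(cfg, alpha_grid = cfg$alpha, n_reps = 10,
                              seed = NULL, shrink_prior = NULL,
                              shrink_ascertain = "pvalue") {
  stopifnot(inherits(cfg, "pgs_config"), n_reps >= 1)
  seeds <- derive_seeds(seed, length(alpha_grid) * n_reps)
  out <- list()
  i <- 0L
  for (a in alpha_grid) {
    cfg_a <- cfg
    cfg_a$alpha <- a
    for (rep in seq_len(n_reps)) {
      i <- i + 1L
      res <- run_pgs_rep(cfg_a, seed = if (is.null(seeds)) NULL else seeds[i],
                         shrink_prior = shrink_prior,
                         shrink_ascertain = shrink_ascertain)
      res$alpha <- a
      res$rep <- rep
      out[[i]] <- res
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("alpha", "rep", "strategy", "context", "pearson_r")]
  class(res) <- c("pgs_grid", "data.frame")
  res
}

#' Aggregate strategy-grid results
#'
#' @param grid Result of [run_strategy_grid()].
#' @return Data frame with per (alpha, strategy, context) mean correlation
#'   and its Monte-Carlo standard error.
#' @export
summarize_strategy_grid <- function(grid) {
  key <- interaction(grid$alpha, grid$strategy, grid$context, drop = TRUE)
  agg <- do.call(rbind, lapply(split(grid, key), function(d) {
    data.frame(alpha = d$alpha[1], strategy = d$strategy[1],
               context = d$context[1],
               mean_r = mean(d$pearson_r),
               mc_se = stats::sd(d$pearson_r) / sqrt(nrow(d)),
               n_reps = nrow(d))
  }))
  rownames(agg) <- NULL
  agg[order(agg$alpha, agg$context, agg$strategy), ]
}
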