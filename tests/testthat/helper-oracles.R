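# Shared simulation helpers and independent oracles.

# Draw a non-degenerate two-context sample from the generative model
# y ~ N(alpha + beta * g, sigma^2) with binomial(2, f) genotypes.
sim_two_context <- function(n, m, betaA, betaB, f = 0.3,
                            sigmaA = 1, sigmaB = 1) {
  repeat {
    gA <- rbinom(n, 2, f)
    gB <- rbinom(m, 2, f)
    if (var(gA) > 0 && var(gB) > 0) break
  }
  stratified_sample(gA, betaA * gA + rnorm(n, 0, sigmaA),
                    gB, betaB * gB + rnorm(m, 0, sigmaB))
}

# Monte-Carlo oracle for the decision rule: at fixed genotypes, compare the
# empirical MSEs of the stratified and pooled (within-context centered)
# estimators for the context-A effect against the analytic prediction.
# Fully vectorized over replicates; independent of the decision-rule code
# except for the analytic quantities it is checking.
decision_mc_oracle <- function(betaA, betaB, f, n, m, sigma = 1, R = 20000) {
  repeat {
    gA <- rbinom(n, 2, f)
    gB <- rbinom(m, 2, f)
    if (var(gA) > 0 && var(gB) > 0) break
  }
  ssA <- sum((gA - mean(gA))^2)
  ssB <- sum((gB - mean(gB))^2)
  VA <- sigma^2 / ssA
  VB <- sigma^2 / ssB
  w <- combination_weights(gA, gB)
  d <- decision_inputs(betaA, betaB, VA, VB, w)
  mse <- evaluate_mse(d)

  YA <- matrix(betaA * gA, n, R) + matrix(rnorm(n * R, 0, sigma), n, R)
  YB <- matrix(betaB * gB, m, R) + matrix(rnorm(m * R, 0, sigma), m, R)
  bA <- as.vector(crossprod(gA - mean(gA), YA)) / ssA
  YAc <- sweep(YA, 2, colMeans(YA))
  YBc <- sweep(YB, 2, colMeans(YB))
  gp <- c(gA, gB)
  gpc <- gp - mean(gp)
  bP <- as.vector(crossprod(gpc, rbind(YAc, YBc))) / sum(gpc^2)
  errs <- (bP - betaA)^2 - (bA - betaA)^2
  list(analytic_diff = unname(mse[["mse_additive"]] - mse[["mse_gxe"]]),
       empirical_diff = mean(errs),
       mc_se = sd(errs) / sqrt(R),
       decision = prefer_gxe(d))
}

# Brute-force 2D grid-integration posterior mean/sd for a single bivariate
# normal prior N(0, U) and likelihood N(bhat; beta, diag(se^2)).
quadrature_posterior <- function(bhat, se, U, half_width = 6, steps = 401) {
  sd1 <- sqrt(U[1, 1] + se[1]^2)
  sd2 <- sqrt(U[2, 2] + se[2]^2)
  b1 <- seq(-half_width * sd1, half_width * sd1, length.out = steps)
  b2 <- seq(-half_width * sd2, half_width * sd2, length.out = steps)
  gr <- expand.grid(b1 = b1, b2 = b2)
  Ui <- solve(U + diag(1e-12, 2))
  quad <- Ui[1, 1] * gr$b1^2 + 2 * Ui[1, 2] * gr$b1 * gr$b2 + Ui[2, 2] * gr$b2^2
  logw <- -0.5 * quad +
    dnorm(bhat[1], gr$b1, se[1], log = TRUE) +
    dnorm(bhat[2], gr$b2, se[2], log = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  c(mean1 = sum(w * gr$b1), mean2 = sum(w * gr$b2))
}

# Write a small well-formed summary-statistics TSV; returns the path.
write_toy_sumstats <- function(path, n_var = 5, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    variant_id = sprintf("rs%d", seq_len(n_var)),
    beta_A = rnorm(n_var, 0, 0.1), se_A = runif(n_var, 0.02, 0.05),
    n_A = 1000, af_A = runif(n_var, 0.1, 0.5),
    beta_B = rnorm(n_var, 0, 0.1), se_B = runif(n_var, 0.02, 0.05),
    n_B = 1500, af_B = runif(n_var, 0.1, 0.5))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
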