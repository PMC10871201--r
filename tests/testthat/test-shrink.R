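test_that("prior grid emits the expected components", {
  g0 <- prior_grid(scales = 1, patterns = "equal")
  expect_named(g0, c("null", "equal_s1"))
  expect_equal(g0$null, matrix(0, 2, 2))
  expect_equal(g0$equal_s1, matrix(1, 2, 2))

  g <- prior_grid(scales = c(0.1, 0.2),
                  patterns = c("equal", "A_only", "B_only", "amplified"),
                  amp_ratios = 1.5, amp_corrs = 1)
  expect_length(g, 9)  # 2 scales x 4 patterns + one null
  expect_equal(g$A_only_s0.1, 0.01 * diag(c(1, 0)))
  amp <- g$amp_a1.5_rho1_s0.2
  expect_equal(amp, 0.04 * matrix(c(2.25, 1.5, 1.5, 1), 2, 2))

  expect_error(prior_grid(numeric(0)), "non-empty")
})

test_that("marginal log-likelihood matches closed-form densities", {
  set.seed(21)
  n <- 50
  bhat <- matrix(rnorm(2 * n, 0, 0.1), n, 2)
  shat <- matrix(runif(2 * n, 0.02, 0.08), n, 2)

  # null-only prior: product of independent normal densities
  nullp <- list(null = matrix(0, 2, 2))
  ll <- marginal_loglik(bhat, shat, nullp, weights = 1)
  expect_equal(ll, sum(dnorm(bhat, 0, shat, log = TRUE)), tolerance = 1e-10)

  # single non-null component: direct bivariate density evaluation
  U <- matrix(c(0.04, 0.02, 0.02, 0.09), 2, 2)
  ll1 <- marginal_loglik(bhat, shat, list(U = U), weights = 1)
  direct <- sum(vapply(seq_len(n), function(j) {
    S <- U + diag(shat[j, ]^2)
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(bhat[j, ] %*% solve(S) %*% bhat[j, ])
  }, numeric(1)))
  expect_equal(ll1, direct, tolerance = 1e-10)

  expect_error(marginal_loglik(bhat, abs(shat) * 0, nullp, 1), "positive")
})

test_that("EM is monotone, stays on the simplex, and recovers weights", {
  set.seed(22)
  p <- 20000
  comps <- list(null = matrix(0, 2, 2), equal = 0.01 * matrix(1, 2, 2))
  null <- runif(p) < 0.5
  truth <- matrix(0, p, 2)
  shared <- rnorm(sum(!null), sd = 0.1)
  truth[!null, ] <- cbind(shared, shared)
  ses <- matrix(runif(2 * p, 0.01, 0.03), p, 2)
  est <- truth + matrix(rnorm(2 * p), p, 2) * ses

  fit <- fit_weights_em(est, ses, comps)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$weights >= 0))
  expect_equal(unname(fit$weights["null"]), 0.5, tolerance = 0.05)
  expect_equal(fit$loglik, marginal_loglik(est, ses, comps, fit$weights),
               tolerance = 1e-8)

  # all-zero estimates with a diffuse alternative: the null dominates
  z <- matrix(0, 200, 2)
  zs <- matrix(0.05, 200, 2)
  fit0 <- fit_weights_em(z, zs, list(null = matrix(0, 2, 2),
                                     wide = diag(2)))
  expect_gt(fit0$weights["null"], 0.99)
})

test_that("single-component data concentrates the fitted weight", {
  set.seed(23)
  p <- 50000
  U <- 0.01 * matrix(c(2.25, 1.5, 1.5, 1), 2, 2)   # amplified, ratio 1.5
  truth <- rbvn(p, cov = U)
  ses <- matrix(0.02, p, 2)
  est <- truth + matrix(rnorm(2 * p, 0, 0.02), p, 2)
  comps <- prior_grid(scales = 0.1,
                      patterns = c("equal", "A_only", "B_only", "amplified"),
                      amp_ratios = 1.5)
  fit <- fit_weights_em(est, ses, comps)
  expect_gte(unname(fit$weights["amp_a1.5_rho1_s0.1"]), 0.95)
})

test_that("posterior effects match conjugate closed forms and quadrature", {
  # null-only prior shrinks everything to zero
  post0 <- posterior_effects(matrix(c(0.1, -0.2), 1, 2),
                             matrix(0.05, 1, 2),
                             list(null = matrix(0, 2, 2)), 1)
  expect_equal(post0$post_mean_A, 0)
  expect_equal(post0$post_mean_B, 0)
  expect_equal(post0$pseudo_p_A, 1)

  # scalar prior u^2 I: per-coordinate shrinkage factor u^2 / (u^2 + s^2)
  u <- 0.1; s <- 0.05
  b <- matrix(c(0.12, -0.3), 1, 2)
  post1 <- posterior_effects(b, matrix(s, 1, 2),
                             list(U = u^2 * diag(2)), 1)
  k <- u^2 / (u^2 + s^2)
  expect_equal(post1$post_mean_A, k * b[1], tolerance = 1e-12)
  expect_equal(post1$post_mean_B, k * b[2], tolerance = 1e-12)
  expect_equal(post1$post_sd_A, sqrt(k * s^2), tolerance = 1e-12)

  # full-matrix prior vs brute-force grid integration
  U <- matrix(c(0.04, 0.03, 0.03, 0.09), 2, 2)
  se <- c(0.05, 0.1)
  bhat <- c(0.12, -0.05)
  post2 <- posterior_effects(matrix(bhat, 1, 2), matrix(se, 1, 2),
                             list(U = U), 1)
  quad <- quadrature_posterior(bhat, se, U)
  expect_equal(post2$post_mean_A, unname(quad["mean1"]), tolerance = 1e-3)
  expect_equal(post2$post_mean_B, unname(quad["mean2"]), tolerance = 1e-3)

  expect_error(posterior_effects(matrix(0, 1, 2), matrix(0, 1, 2),
                                 list(null = matrix(0, 2, 2)), 1),
               "positive")
})

test_that("amplification prior pulls posterior ratios toward the prior ratio", {
  set.seed(24)
  p <- 2000
  U <- 0.01 * matrix(c(1, 1.4, 1.4, 1.96), 2, 2)  # B amplified 1.4x
  truth <- rbvn(p, cov = U)
  ses <- matrix(0.08, p, 2)   # low per-variant signal
  est <- truth + matrix(rnorm(2 * p, 0, 0.08), p, 2)
  post <- posterior_effects(est, ses, list(U = U), 1)
  ratio <- post$post_mean_B / post$post_mean_A
  expect_equal(median(ratio), 1.4, tolerance = 0.05)
})

test_that("gxe_shrink returns a complete model object with methods", {
  set.seed(25)
  p <- 500
  shared <- rnorm(p, sd = 0.1)
  truth <- cbind(shared, shared)
  ses <- matrix(0.05, p, 2)
  est <- truth + matrix(rnorm(2 * p, 0, 0.05), p, 2)
  fit <- gxe_shrink(est, ses, prior = prior_grid(c(0.05, 0.1, 0.2)))

  expect_s3_class(fit, "gxe_shrink")
  expect_true(fit$converged)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_equal(dim(fitted(fit)), c(p, 2))
  expect_equal(residuals(fit), est - fitted(fit))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "mixture weights")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gxe_shrink")
  expect_equal(sum(sm$weights_by_pattern), 1, tolerance = 1e-12)

  # posterior means are shrunk toward the equal-effects diagonal
  expect_lt(mean((fitted(fit) - truth)^2), mean((est - truth)^2))

  # predict on new data equals direct posterior computation
  nd <- list(bhat = est[1:10, ], shat = ses[1:10, ])
  expect_equal(predict(fit, nd),
               posterior_effects(nd$bhat, nd$shat, fit$prior, coef(fit)))
  expect_identical(predict(fit), fit$posterior)
})
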