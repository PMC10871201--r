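test_that("combination weights follow the sums-of-squares formula", {
  # symmetric contexts: equal weights summing to 1
  w <- combination_weights(c(0, 1, 2, 1), c(1, 0, 2, 1))
  expect_equal(w$omega_A, 0.5)
  expect_equal(w$omega_B, 0.5)

  # equal means, ss_A = 2, ss_B = 4, pooled = 6
  w <- combination_weights(c(0, 2), c(0, 0, 2, 2))
  expect_equal(w$omega_A, 1 / 3)
  expect_equal(w$omega_B, 2 / 3)

  # equal heterozygosity and means: omega_A = n / (n + m)
  gA <- rep(c(0, 1, 1, 2), 25)   # n = 100, f = 0.5
  gB <- rep(c(0, 1, 1, 2), 75)   # m = 300, f = 0.5
  w <- combination_weights(gA, gB)
  expect_equal(w$omega_A, 0.25)
  expect_equal(w$het_A, 0.5)

  # unequal context means: weights need not sum to 1
  w <- combination_weights(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_lt(w$omega_A + w$omega_B, 1)
  expect_true(w$omega_A >= 0 && w$omega_B >= 0)

  expect_error(combination_weights(c(1, 1), c(1, 1)), "degenerate")
})

test_that("MSE evaluation and the preference rule follow the bias-variance split", {
  w5 <- approx_weights(100, 100, 0.5, 0.5)  # omega = 0.5 / 0.5

  # worked case: bias^2 = 0.25, variance = 0.05 vs V_A = 0.1
  d <- decision_inputs(1, 0, 0.1, 0.1, w5)
  mse <- evaluate_mse(d)
  expect_equal(unname(mse["mse_additive"]), 0.30)
  expect_equal(unname(mse["mse_gxe"]), 0.10)
  expect_identical(prefer_gxe(d), "GXE")

  # equal effects with weights summing to 1: zero bias, additive wins
  d0 <- decision_inputs(0.4, 0.4, 0.2, 0.2, w5)
  mse0 <- evaluate_mse(d0)
  expect_equal(unname(mse0["mse_additive"]), 0.25 * 0.2 + 0.25 * 0.2)
  expect_identical(prefer_gxe(d0), "ADDITIVE")

  # noiseless limit with differing effects: GxE is exact
  dn <- decision_inputs(1, 0.5, 0, 0, w5)
  msen <- evaluate_mse(dn)
  expect_equal(unname(msen["mse_gxe"]), 0)
  expect_gt(unname(msen["mse_additive"]), 0)
  expect_identical(prefer_gxe(dn), "GXE")

  # exact equality: solve for var_A at beta = (1, 0), omega = 0.5, VB = VA
  # 0.25 + 0.5 vA = vA  =>  vA = 0.5
  dt <- decision_inputs(1, 0, 0.5, 0.5, w5)
  expect_identical(prefer_gxe(dt), "TIE")
})

test_that("signal-to-noise rule agrees with the MSE rule when weights sum to 1", {
  # fixed arithmetic: omega = 0.5, VB = VA gives threshold 3 - 1 = 2
  expect_identical(snr_decision(1, 1 - sqrt(2.0001), 1, 1, 0.5), "GXE")
  expect_identical(snr_decision(1, 1 - sqrt(1.9999), 1, 1, 0.5), "ADDITIVE")

  set.seed(7)
  for (i in 1:200) {
    omega <- runif(1, 0.05, 0.95)
    d <- decision_inputs(rnorm(1), rnorm(1), runif(1, 0.01, 2),
                         runif(1, 0.01, 2),
                         list(omega_A = omega, omega_B = 1 - omega))
    expect_identical(snr_decision(d$beta_A, d$beta_B, d$var_A, d$var_B, omega),
                     prefer_gxe(d))
  }
  expect_error(snr_decision(1, 0, 1, 1, 1.2), "omega_A")
})

test_that("decision statistic re-parameterization is exact", {
  # (mse_additive - V_A) / V_A  ==  omega_B^2 * (snr_lhs - snr_rhs)
  set.seed(8)
  for (i in 1:100) {
    omega <- runif(1, 0.05, 0.95)
    bA <- rnorm(1); bB <- rnorm(1)
    vA <- runif(1, 0.01, 2); vB <- runif(1, 0.01, 2)
    d <- decision_inputs(bA, bB, vA, vB,
                         list(omega_A = omega, omega_B = 1 - omega))
    mse <- evaluate_mse(d)
    lhs <- (bA - bB)^2 / vA
    rhs <- (1 + omega) / (1 - omega) - vB / vA
    stat4 <- (mse[["mse_additive"]] - vA) / vA
    stat6 <- (1 - omega)^2 * (lhs - rhs)
    expect_equal(stat4, stat6, tolerance = 1e-12)
  }
})

test_that("never-additive threshold matches the sign of the SNR bound", {
  expect_equal(never_additive_threshold(0.5), 1 / 3)
  expect_equal(never_additive_threshold(0.8), 1 / 9, tolerance = 1e-12)
  # limit: as omega_A -> 0 the threshold approaches 1
  expect_equal(never_additive_threshold(1e-9), 1, tolerance = 1e-8)
  expect_error(never_additive_threshold(0), "omega_A")
  expect_error(never_additive_threshold(1), "omega_A")

  for (omega in seq(0.05, 0.95, by = 0.05)) {
    r_star <- never_additive_threshold(omega)
    for (r in seq(0.02, 1.5, by = 0.02)) {
      rhs <- (1 + omega) / (1 - omega) - 1 / r   # V_B / V_A = 1 / r
      expect_identical(rhs < 0, r < r_star - 1e-12)
    }
  }
})

test_that("sd-units boundary coincides with MSE equality at r = 1", {
  expect_equal(boundary_sd(1, 100, 100), sqrt(0.5))
  expect_equal(boundary_sd(0, 50, 200), 0)

  set.seed(9)
  for (i in 1:50) {
    n <- sample(20:500, 1); m <- sample(20:500, 1)
    delta <- runif(1, 0.01, 2)
    sd_star <- boundary_sd(delta, n, m)
    vA <- sd_star^2
    omega <- n / (n + m)
    d <- decision_inputs(delta, 0, vA, vA,
                         list(omega_A = omega, omega_B = 1 - omega))
    mse <- evaluate_mse(d)
    expect_equal(mse[["mse_additive"]], mse[["mse_gxe"]],
                 tolerance = 1e-12)
    # just below the boundary the GxE estimator wins
    d2 <- decision_inputs(delta, 0, (0.99 * sd_star)^2, (0.99 * sd_star)^2,
                          list(omega_A = omega, omega_B = 1 - omega))
    expect_identical(prefer_gxe(d2), "GXE")
  }
})

test_that("decision rule matches empirical MSEs at a few simulated points", {
  set.seed(10)
  cases <- list(c(betaA = 0.4, betaB = -0.4, f = 0.3, n = 80, m = 120),
                c(betaA = 0.1, betaB = 0.12, f = 0.4, n = 100, m = 100),
                c(betaA = 0, betaB = 0, f = 0.25, n = 60, m = 180))
  for (cs in cases) {
    o <- decision_mc_oracle(cs[["betaA"]], cs[["betaB"]], cs[["f"]],
                            cs[["n"]], cs[["m"]], R = 5000)
    if (abs(o$analytic_diff) > 3 * o$mc_se)
      expect_identical(sign(o$analytic_diff), sign(o$empirical_diff))
  }
})

test_that("summary-statistics screen applies the plug-in rule row-wise", {
  tab <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    beta_A = c(0.05, 0.5, 0.05), se_A = c(0.05, 0.05, 0.05),
    n_A = 1000, af_A = 0.3,
    beta_B = c(0.05, 0.0, 0.05), se_B = c(0.05, 0.05, -1),
    n_B = 1000, af_B = 0.3)

  expect_warning(res <- decision_screen(tab, focal = "A"), "non-positive")
  expect_equal(nrow(res), 2)
  # equal estimates: additive for any positive noise
  expect_identical(res$decision[1], "ADDITIVE")
  # difference of 10 standard errors: GxE
  expect_identical(res$decision[2], "GXE")
  expect_equal(res$omega_A, c(0.5, 0.5))
  expect_equal(res$mse_gxe, c(0.0025, 0.0025))

  # without the moment correction the squared difference is used as-is
  raw <- decision_screen(tab[1:2, ], focal = "A", bias_correct = FALSE)
  expect_equal(raw$mse_additive[2],
               0.25 * 0.25 + 0.25 * 0.0025 + 0.25 * 0.0025)

  # r_proxy overrides the other context's variance
  rp <- decision_screen(tab[1:2, ], focal = "A", r_proxy = 0.5)
  expect_equal(rp$mse_additive[1], 0.25 * 0.0025 + 0.25 * 0.005)

  expect_error(decision_screen(tab[, -2]), "missing required")
})

test_that("bias-corrected squared difference is unbiased for the true signal", {
  # signal well above noise so the floor at zero almost never binds and the
  # moment correction is effectively unbiased
  set.seed(11)
  bA <- 0.3; bB <- 0.1
  R <- 40000
  seA <- 0.02; seB <- 0.03
  tab <- data.frame(
    variant_id = sprintf("v%d", 1:R),
    beta_A = rnorm(R, bA, seA), se_A = seA, n_A = 1000, af_A = 0.3,
    beta_B = rnorm(R, bB, seB), se_B = seB, n_B = 1000, af_B = 0.3)
  res <- decision_screen(tab, focal = "A", bias_correct = TRUE)
  # recover the corrected (beta_A - beta_B)^2 from the bias^2 term
  diff2 <- res$mse_additive - res$omega_A^2 * seA^2 - (1 - res$omega_A)^2 * seB^2
  mean_corrected <- mean(diff2) / mean((1 - res$omega_A)^2)
  expect_equal(mean_corrected, (bA - bB)^2, tolerance = 0.01)
})
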