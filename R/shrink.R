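#' Covariance grid for the two-context mixture prior
#'
#' Builds the fixed covariance components of the zero-centered bivariate
#' normal mixture prior used by [gxe_shrink()]. For each scale `s` (a prior
#' effect standard deviation, in effect units) one component is emitted per
#' requested pattern:
#' \describe{
#'   \item{equal}{`s^2 * [[1, 1], [1, 1]]` — identical effects in both
#'     contexts.}
#'   \item{A_only}{`s^2 * [[1, 0], [0, 0]]` — effect only in context A.}
#'   \item{B_only}{`s^2 * [[0, 0], [0, 1]]` — effect only in context B.}
#'   \item{amplified}{`s^2 * [[a^2, rho * a], [rho * a, 1]]` for each
#'     amplification ratio `a` (sd in context A relative to B) in
#'     `amp_ratios` and correlation `rho` in `amp_corrs`.}
#' }
#' A single null (zero-matrix) component is always included first.
#'
#' @param scales Positive numeric vector of prior effect sds.
#' @param patterns Subset of `c("equal", "A_only", "B_only", "amplified")`.
#' @param amp_ratios Amplification ratios for the `"amplified"` pattern.
#' @param amp_corrs Cross-context correlations for the `"amplified"` pattern.
#' @return Object of class `"prior_grid"`: a named list of 2x2 covariance
#'   matrices, first component `"null"`.
#' @examples
#' prior_grid(scales = c(0.1, 0.2),
#'            patterns = c("equal", "A_only", "B_only", "amplified"),
#'            amp_ratios = 1.5)
#' @export
prior_grid <- function(scales,
                       patterns = c("equal", "A_only", "B_only", "amplified"),
                       amp_ratios = c(1.5, 1 / 1.5),
                       amp_corrs = 1) {
  if (length(scales) == 0L) stop("`scales` must be non-empty")
  stopifnot(all(scales > 0))
  patterns <- match.arg(patterns, several.ok = TRUE)
  comps <- list(null = matrix(0, 2, 2))
  for (s in scales) {
    s2 <- s^2
    for (p in patterns) {
      if (p == "equal") {
        comps[[sprintf("equal_s%g", s)]] <- s2 * matrix(1, 2, 2)
      } else if (p == "A_only") {
        comps[[sprintf("A_only_s%g", s)]] <- s2 * diag(c(1, 0))
      } else if (p == "B_only") {
        comps[[sprintf("B_only_s%g", s)]] <- s2 * diag(c(0, 1))
      } else {
        for (a in amp_ratios) for (rho in amp_corrs) {
          comps[[sprintf("amp_a%g_rho%g_s%g", a, rho, s)]] <-
            s2 * matrix(c(a^2, rho * a, rho * a, 1), 2, 2)
        }
      }
    }
  }
  structure(comps, class = "prior_grid")
}

#' Default data-driven scale grid
#'
#' Geometric grid of prior effect sds spanning from well below the median
#' standard error (effects indistinguishable from null) to the largest
#' observed estimate magnitude.
#'
#' @param bhat,shat Two-column matrices of estimates and standard errors.
#' @param length_out Number of scales.
#' @return Numeric vector of scales.
#' @export
auto_scales <- function(bhat, shat, length_out = 8) {
  bhat <- as_two_col_matrix(bhat); shat <- as_two_col_matrix(shat)
  lo <- stats::median(shat) / 4
  hi <- max(abs(bhat), lo * 2)
  exp(seq(log(lo), log(hi), length.out = length_out))
}

# Per-row mixture component log-likelihood matrix: L[j, k] = log density of
# bhat_j under N(0, U_k + diag(shat_j^2)).
component_logliks <- function(bhat, shat, components) {
  x1 <- bhat[, 1]; x2 <- bhat[, 2]
  s1 <- shat[, 1]^2; s2 <- shat[, 2]^2
  matrix(vapply(components, function(U) {
    bvn_logdens(x1, x2, U[1, 1] + s1, U[1, 2], U[2, 2] + s2)
  }, numeric(length(x1))), nrow = length(x1))
}

#' Marginal log-likelihood of a weighted mixture prior
#'
#' Evaluates `sum_j log sum_k w_k phi2(bhat_j; 0, U_k + S_j)` where `S_j` is
#' the diagonal matrix of squared standard errors of variant `j` (errors
#' independent across contexts).
#'
#' @param bhat,shat Two-column matrices (variants x contexts) of effect
#'   estimates and positive standard errors.
#' @param prior A `"prior_grid"` (or list of 2x2 covariance matrices).
#' @param weights Mixture weights on the simplex, one per component.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(bhat, shat, prior, weights) {
  bhat <- as_two_col_matrix(bhat); shat <- as_two_col_matrix(shat)
  if (!all(is.finite(bhat)) || !all(is.finite(shat)))
    stop("non-finite estimates or standard errors")
  if (any(shat <= 0)) stop("standard errors must be positive")
  stopifnot(length(weights) == length(prior), all(weights >= 0))
  ll <- component_logliks(bhat, shat, prior)
  sum(logsumexp_rows(ll, weights))
}

# log sum_k w_k exp(ll[, k]) row-wise, guarding w_k = 0
logsumexp_rows <- function(ll, weights) {
  lw <- ifelse(weights > 0, log(weights), -Inf)
  a <- sweep(ll, 2, lw, "+")
  mx <- apply(a, 1, max)
  mx + log(rowSums(exp(a - mx)))
}

#' Fit mixture weights by expectation-maximization
#'
#' Maximizes the marginal likelihood over the weight simplex with the
#' covariance components held fixed. Deterministic given the data (uniform
#' initialization).
#'
#' @inheritParams marginal_loglik
#' @param components A `"prior_grid"` or list of 2x2 covariance matrices.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations; non-convergence warns and returns
#'   the final iterate.
#' @return List with `weights` (named), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`.
#' @export
fit_weights_em <- function(bhat, shat, components, tol = 1e-6,
                           max_iter = 1000L) {
  bhat <- as_two_col_matrix(bhat); shat <- as_two_col_matrix(shat)
  if (nrow(bhat) < 1L) stop("need at least one variant")
  if (length(components) < 1L) stop("need at least one component")
  if (any(shat <= 0)) stop("standard errors must be positive")
  K <- length(components)
  ll <- component_logliks(bhat, shat, components)
  w <- rep(1 / K, K)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- ifelse(w > 0, log(w), -Inf)
    a <- sweep(ll, 2, lw, "+")
    mx <- apply(a, 1, max)
    lse <- mx + log(rowSums(exp(a - mx)))
    cur <- sum(lse)
    trace <- c(trace, cur)
    resp <- exp(a - lse)          # responsibilities, rows sum to 1
    w <- colMeans(resp)
    w <- w / sum(w)
    if (is.finite(prev) &&
        abs(cur - prev) <= tol * (abs(prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations; returning final iterate",
                    max_iter))
  # report the log-likelihood at the returned weights (one final E-step)
  trace <- c(trace, sum(logsumexp_rows(ll, w)))
  names(w) <- names(components)
  list(weights = w, loglik = trace[length(trace)], loglik_trace = trace,
       n_iter = length(trace) - 1L, converged = converged)
}

#' Posterior effect summaries under a fitted mixture prior
#'
#' For each variant, combines the conjugate component posteriors
#' (mean `U_k (U_k + S_j)^{-1} bhat_j`, covariance
#' `U_k - U_k (U_k + S_j)^{-1} U_k`) with posterior component
#' responsibilities into a mixture posterior mean and covariance. Per-context
#' pseudo p-values are the two-sided normal tails of the posterior z-scores
#' `|post_mean| / post_sd`; they are ranking statistics, not calibrated
#' frequentist p-values.
#'
#' @inheritParams marginal_loglik
#' @return Data frame with one row per variant: `post_mean_A`, `post_mean_B`,
#'   `post_sd_A`, `post_sd_B`, `post_cov_AB`, `pseudo_p_A`, `pseudo_p_B`.
#' @export
posterior_effects <- function(bhat, shat, prior, weights) {
  bhat <- as_two_col_matrix(bhat); shat <- as_two_col_matrix(shat)
  if (any(shat <= 0)) stop("standard errors must be positive (singular posterior otherwise)")
  stopifnot(length(weights) == length(prior))
  J <- nrow(bhat)
  ll <- component_logliks(bhat, shat, prior)
  lw <- ifelse(weights > 0, log(weights), -Inf)
  a <- sweep(ll, 2, lw, "+")
  mx <- apply(a, 1, max)
  resp <- exp(a - (mx + log(rowSums(exp(a - mx)))))

  x1 <- bhat[, 1]; x2 <- bhat[, 2]
  s1 <- shat[, 1]^2; s2 <- shat[, 2]^2
  m1 <- m2 <- v11 <- v22 <- v12 <- numeric(J)   # E[beta], E[beta beta^T] accumulators
  for (k in seq_along(prior)) {
    U <- prior[[k]]
    rk <- resp[, k]
    if (all(rk == 0)) next
    u11 <- U[1, 1]; u12 <- U[1, 2]; u22 <- U[2, 2]
    A <- u11 + s1; B <- u12; C <- u22 + s2
    det <- A * C - B^2
    # K = U (U + S)^-1, with (U+S)^-1 = [[C, -B], [-B, A]] / det
    k11 <- (u11 * C - u12 * B) / det
    k12 <- (-u11 * B + u12 * A) / det
    k21 <- (u12 * C - u22 * B) / det
    k22 <- (-u12 * B + u22 * A) / det
    mu1 <- k11 * x1 + k12 * x2
    mu2 <- k21 * x1 + k22 * x2
    c11 <- u11 - (k11 * u11 + k12 * u12)
    c12 <- u12 - (k11 * u12 + k12 * u22)
    c22 <- u22 - (k21 * u12 + k22 * u22)
    m1 <- m1 + rk * mu1
    m2 <- m2 + rk * mu2
    v11 <- v11 + rk * (c11 + mu1^2)
    v22 <- v22 + rk * (c22 + mu2^2)
    v12 <- v12 + rk * (c12 + mu1 * mu2)
  }
  v11 <- pmax(v11 - m1^2, 0)
  v22 <- pmax(v22 - m2^2, 0)
  v12 <- v12 - m1 * m2
  pseudo_p <- function(m, v) {
    sd <- sqrt(v)
    p <- ifelse(sd > 0, 2 * stats::pnorm(-abs(m) / sd), ifelse(m == 0, 1, 0))
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  data.frame(post_mean_A = m1, post_mean_B = m2,
             post_sd_A = sqrt(v11), post_sd_B = sqrt(v22),
             post_cov_AB = v12,
             pseudo_p_A = pseudo_p(m1, v11),
             pseudo_p_B = pseudo_p(m2, v22))
}

#' Empirical-Bayes multivariate shrinkage of two-context effect estimates
#'
#' Fits a zero-centered bivariate normal mixture prior (fixed covariance
#' components, free weights) to paired effect estimates by maximum marginal
#' likelihood, then shrinks each variant's estimates toward the genome-wide
#' covariance patterns the data support. This is a simplified two-context
#' multivariate adaptive shrinkage: the prior grid is fixed (see
#' [prior_grid()]) and only mixture weights are learned.
#'
#' @param bhat Matrix or data frame of effect estimates, one row per variant,
#'   columns = contexts A and B.
#' @param shat Matching matrix of positive standard errors.
#' @param prior Optional `"prior_grid"`; defaults to [prior_grid()] over
#'   [auto_scales()] with all four patterns.
#' @param tol,max_iter EM convergence controls (relative log-likelihood
#'   change; iteration cap).
#' @return Object of class `"gxe_shrink"`: list with `weights`, `prior`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `posterior` (the
#'   [posterior_effects()] data frame for the training variants), `data`,
#'   and `call`.
#' @seealso [predict.gxe_shrink()], [coef.gxe_shrink()]
#' @examples
#' set.seed(1)
#' b <- matrix(rnorm(400, sd = 0.1), ncol = 2); b[, 2] <- b[, 1]
#' s <- matrix(0.05, nrow = 200, ncol = 2)
#' fit <- gxe_shrink(b + rnorm(400, sd = 0.05), s,
#'                   prior = prior_grid(c(0.05, 0.1, 0.2)))
#' summary(fit)
#' @export
gxe_shrink <- function(bhat, shat, prior = NULL, tol = 1e-6, max_iter = 1000L) {
  cl <- match.call()
  bhat <- as_two_col_matrix(bhat); shat <- as_two_col_matrix(shat)
  if (nrow(bhat) != nrow(shat)) stop("bhat and shat must have the same rows")
  if (is.null(prior)) prior <- prior_grid(auto_scales(bhat, shat))
  em <- fit_weights_em(bhat, shat, prior, tol = tol, max_iter = max_iter)
  post <- posterior_effects(bhat, shat, prior, em$weights)
  structure(
    list(weights = em$weights, prior = prior, loglik = em$loglik,
         loglik_trace = em$loglik_trace, n_iter = em$n_iter,
         converged = em$converged, posterior = post,
         data = list(bhat = bhat, shat = shat), call = cl),
    class = "gxe_shrink")
}

#' @export
print.gxe_shrink <- function(x, ...) {
  cat("Empirical-Bayes two-context shrinkage fit\n")
  cat(sprintf("  %d variants, %d prior components, log-likelihood %.2f (%d EM iterations)\n",
              nrow(x$data$bhat), length(x$prior), x$loglik, x$n_iter))
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[top > 0.01]
  cat("  leading mixture weights:\n")
  for (nm in names(top)) cat(sprintf("    %-20s %.3f\n", nm, top[[nm]]))
  invisible(x)
}

#' @export
summary.gxe_shrink <- function(object, ...) {
  w <- object$weights
  pat <- sub("_s[0-9.eE+-]+$", "", names(w))
  pat <- sub("_rho[0-9.eE+-]+$", "", pat)
  by_pattern <- tapply(w, pat, sum)
  out <- list(weights = w, weights_by_pattern = by_pattern,
              loglik = object$loglik, n_iter = object$n_iter,
              converged = object$converged,
              n_variants = nrow(object$data$bhat))
  class(out) <- "summary.gxe_shrink"
  out
}

#' @export
print.summary.gxe_shrink <- function(x, ...) {
  cat(sprintf("Shrinkage fit on %d variants (log-likelihood %.2f, %s)\n",
              x$n_variants, x$loglik,
              if (x$converged) "converged" else "not converged"))
  cat("Mixture weight by covariance pattern:\n")
  print(round(sort(x$weights_by_pattern, decreasing = TRUE), 4))
  invisible(x)
}

#' @export
coef.gxe_shrink <- function(object, ...) object$weights

#' @export
logLik.gxe_shrink <- function(object, ...) {
  structure(object$loglik, df = length(object$weights) - 1,
            nobs = nrow(object$data$bhat), class = "logLik")
}

#' @export
fitted.gxe_shrink <- function(object, ...) {
  as.matrix(object$posterior[, c("post_mean_A", "post_mean_B")])
}

#' @export
residuals.gxe_shrink <- function(object, ...) {
  object$data$bhat - fitted(object)
}

#' Posterior effects for new (or training) variants
#'
#' @param object A `"gxe_shrink"` fit.
#' @param newdata Optional list with elements `bhat` and `shat` (two-column
#'   matrices); defaults to the training data.
#' @param ... Unused.
#' @return [posterior_effects()] data frame.
#' @export
predict.gxe_shrink <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posterior)
  posterior_effects(newdata$bhat, newdata$shat, object$prior, object$weights)
}
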