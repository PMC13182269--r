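# Random-intercept/random-slope linear mixed model for a single biomarker:
#   y_ij = (b_L0 + b_i0) + (b_L1 + b_i1) * t_ij + e_ij,
#   (b_i0, b_i1) ~ N(0, D), e_ij ~ N(0, sigma2),
# estimated by maximum likelihood (not REML, so that the joint model's
# likelihood separates exactly at association zero).  The marginal
# per-subject likelihood is evaluated from sufficient statistics with the
# Woodbury identity, which keeps the optimisation O(n_subjects) with tiny
# constants and lets the joint model reuse the same machinery.

# Per-subject sufficient statistics for design [1, t].
lmm_suffstats <- function(data) {
  m <- data$measurements
  if (!nrow(m)) stop("no measurements")
  sid <- factor(m$subject_id, levels = unique(m$subject_id))
  list(ids = levels(sid),
       n = as.vector(tapply(m$value, sid, length)),
       St = as.vector(tapply(m$time, sid, sum)),
       Stt = as.vector(tapply(m$time^2, sid, sum)),
       Sy = as.vector(tapply(m$value, sid, sum)),
       Sty = as.vector(tapply(m$time * m$value, sid, sum)),
       Syy = as.vector(tapply(m$value^2, sid, sum)),
       times = split(m$time, sid), values = split(m$value, sid))
}

# theta = (beta0, beta1, l1, l2, l3, log_sigma2); D = L L' with
# L = [[exp(l1), 0], [l2, exp(l3)]] (log-Cholesky, always positive definite).
.lmm_unpack <- function(theta) {
  theta <- unname(theta)
  L <- matrix(c(exp(theta[3]), theta[4], 0, exp(theta[5])), 2, 2)
  list(beta = theta[1:2], D = L %*% t(L), sigma2 = exp(theta[6]))
}

# Vectorised marginal -loglik over subjects given suffstats (needs PD D).
.lmm_nll_fast <- function(theta, ss) {
  p <- .lmm_unpack(theta)
  D <- p$D; s2 <- p$sigma2; b0 <- p$beta[1]; b1 <- p$beta[2]
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  if (!is.finite(detD) || detD <= 0 || !is.finite(s2)) return(1e10)
  Di11 <- D[2, 2] / detD; Di22 <- D[1, 1] / detD; Di12 <- -D[1, 2] / detD
  p11 <- Di11 + ss$n / s2
  p12 <- Di12 + ss$St / s2
  p22 <- Di22 + ss$Stt / s2
  detP <- p11 * p22 - p12^2
  if (any(!is.finite(detP) | detP <= 0)) return(1e10)
  u1 <- ss$Sy - b0 * ss$n - b1 * ss$St
  u2 <- ss$Sty - b0 * ss$St - b1 * ss$Stt
  rr <- ss$Syy - 2 * b0 * ss$Sy - 2 * b1 * ss$Sty +
    b0^2 * ss$n + 2 * b0 * b1 * ss$St + b1^2 * ss$Stt
  quad <- (rr - (p22 * u1^2 - 2 * p12 * u1 * u2 + p11 * u2^2) / (detP * s2)) / s2
  logdetV <- log(detP) + log(detD) + ss$n * log(s2)
  nll <- 0.5 * sum(ss$n * log(2 * pi) + logdetV + quad)
  if (!is.finite(nll)) 1e10 else nll
}

# Posterior (empirical Bayes) moments of b_i given the subject's data:
# precision P_i = D^{-1} + Z_i'Z_i/s2, mean mu_i = P_i^{-1} Z_i' r_i / s2.
.lmm_posterior <- function(beta, D, sigma2, ss) {
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  Di11 <- D[2, 2] / detD; Di22 <- D[1, 1] / detD; Di12 <- -D[1, 2] / detD
  p11 <- Di11 + ss$n / sigma2
  p12 <- Di12 + ss$St / sigma2
  p22 <- Di22 + ss$Stt / sigma2
  detP <- p11 * p22 - p12^2
  u1 <- (ss$Sy - beta[1] * ss$n - beta[2] * ss$St) / sigma2
  u2 <- (ss$Sty - beta[1] * ss$St - beta[2] * ss$Stt) / sigma2
  mu1 <- (p22 * u1 - p12 * u2) / detP
  mu2 <- (p11 * u2 - p12 * u1) / detP
  # covariance = P^{-1}
  s11 <- p22 / detP; s22 <- p11 / detP; s12 <- -p12 / detP
  list(mu1 = mu1, mu2 = mu2, s11 = s11, s12 = s12, s22 = s22)
}

#' Marginal log-likelihood of the linear mixed model
#'
#' Sum over subjects of the log multivariate-normal density of the subject's
#' measurement vector with mean `X_i beta` and covariance
#' `Z_i D Z_i' + sigma2 I`, where both designs are `[1, time]`.  Uses a dense
#' per-subject computation, so singular `D` (including `D = 0`) is handled.
#'
#' @param params list with `beta` (length 2), `D` (2x2 symmetric PSD),
#'   `sigma2` (> 0).
#' @param data a [longitudinal_dataset()] restricted to a single feature.
#' @return scalar log-likelihood.
#' @export
lmm_loglik <- function(params, data) {
  D <- params$D; s2 <- params$sigma2; beta <- params$beta
  stopifnot(s2 > 0, length(beta) == 2, all(dim(D) == c(2, 2)))
  if (abs(D[1, 2] - D[2, 1]) > 1e-8 || any(eigen(D, symmetric = TRUE,
                                                 only.values = TRUE)$values < -1e-8))
    stop("D must be symmetric positive semidefinite")
  ss <- lmm_suffstats(data)
  ll <- 0
  for (i in seq_along(ss$ids)) {
    t_i <- ss$times[[i]]; y_i <- ss$values[[i]]
    Z <- cbind(1, t_i)
    V <- Z %*% D %*% t(Z) + s2 * diag(length(t_i))
    r <- y_i - Z %*% beta
    ch <- chol(V)
    ll <- ll - 0.5 * (length(t_i) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  ll
}

#' Fit the linear mixed model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimisation on the log-Cholesky parameterisation of
#' the random-effect covariance; up to three jittered restarts on
#' non-convergence.  Returns empirical-Bayes (BLUP) random-effect estimates
#' per subject.
#'
#' @param data a [longitudinal_dataset()] restricted to a single feature,
#'   with at least 2 subjects and at least 2 distinct measurement times.
#' @param control list: `reltol` (default 1e-10), `maxit` (default 500),
#'   `n_starts` (default 3).
#' @return object of class `lmm_fit`: `beta`, `D`, `sigma2`, `loglik`,
#'   `converged`, `blups` (data.frame subject_id/b0/b1), `theta` (working
#'   parameters), `suffstats`.
#' @export
fit_lmm <- function(data, control = list()) {
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 500, n_starts = 3),
                            control)
  ss <- lmm_suffstats(data)
  if (length(ss$ids) < 2) stop("need at least 2 subjects")
  all_t <- data$measurements$time
  if (length(unique(round(all_t, 10))) < 2)
    stop("all measurement times identical: slope is not identifiable")

  # moment-based start: pooled OLS for beta, residual split between levels
  fit0 <- stats::lm.fit(cbind(1, all_t), data$measurements$value)
  res_var <- max(stats::var(fit0$residuals), 1e-6)
  start <- c(fit0$coefficients,
             log(sqrt(res_var / 2)), 0, log(0.1 * sqrt(res_var / 2) + 1e-4),
             log(res_var / 2))

  best <- NULL
  for (k in seq_len(ctrl$n_starts)) {
    st <- if (k == 1) start else start + stats::rnorm(6, 0, 0.3)
    opt <- try(stats::optim(st, .lmm_nll_fast, ss = ss, method = "BFGS",
                            control = list(reltol = ctrl$reltol,
                                           maxit = ctrl$maxit)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0) break
  }
  if (is.null(best)) stop("LMM optimisation failed from all starts")
  p <- .lmm_unpack(best$par)
  if (p$D[1, 1] < 1e-8 || p$D[2, 2] < 1e-10)
    warning("random-effect variance at/near boundary (singular D)")
  post <- .lmm_posterior(p$beta, p$D, p$sigma2, ss)
  structure(list(beta = p$beta, D = p$D, sigma2 = p$sigma2,
                 loglik = -best$value, converged = best$convergence == 0,
                 blups = data.frame(subject_id = ss$ids,
                                    b0 = post$mu1, b1 = post$mu2),
                 theta = best$par, suffstats = ss,
                 n_subjects = length(ss$ids)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML), ", x$n_subjects, " subjects\n", sep = "")
  cat("  fixed effects:  intercept ", format(x$beta[1], digits = 4),
      ", slope ", format(x$beta[2], digits = 4), "\n", sep = "")
  cat("  random effects: sd(b0) ", format(sqrt(x$D[1, 1]), digits = 4),
      ", sd(b1) ", format(sqrt(x$D[2, 2]), digits = 4),
      ", corr ", format(stats::cov2cor(x$D)[1, 2], digits = 3), "\n", sep = "")
  cat("  sigma ", format(sqrt(x$sigma2), digits = 4),
      ";  logLik ", format(x$loglik, digits = 8),
      ";  converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes random-effect prediction for one subject
#'
#' Closed-form Gaussian posterior mean of `(b0, b1)` given the fitted
#' population parameters and the subject's measurements.  With no
#' measurements the prior mean `(0, 0)` is returned.
#'
#' @param fit an [fit_lmm()] result (or any list with `beta`, `D`, `sigma2`).
#' @param times,values the subject's measurement times and abundances.
#' @return named numeric vector `c(b0, b1)`.
#' @export
predict_blup <- function(fit, times, values) {
  stopifnot(length(times) == length(values))
  if (!length(times)) return(c(b0 = 0, b1 = 0))
  ss <- list(n = length(times), St = sum(times), Stt = sum(times^2),
             Sy = sum(values), Sty = sum(times * values))
  post <- .lmm_posterior(fit$beta, fit$D, fit$sigma2, ss)
  c(b0 = post$mu1, b1 = post$mu2)
}
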