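# Shared fixtures and independent oracles, built in code.

# Small deterministic three-table dataset used by container/landmark tests.
toy_dataset <- function() {
  measurements <- data.frame(
    subject_id = c("a", "a", "a", "b", "b", "c"),
    time = c(0, 2, 4, 0, 3, 1),
    feature_id = "f1",
    value = c(5.0, 5.5, 6.0, 4.0, 4.1, 7.0))
  subjects <- data.frame(
    subject_id = c("a", "b", "c"),
    event_time = c(6, 10, 10),
    status = c(1L, 0L, 0L),
    group = c("case", "control", "control"))
  features <- data.frame(feature_id = "f1", n_peptides = 8L, n_missing = 0L)
  longitudinal_dataset(measurements, subjects, features)
}

# Reference parameters used across joint-model tests (moderate association,
# baseline calibrated so events cluster late in a 20-year study).
ref_theta <- function(alpha = 0.8) {
  list(beta = c(6, 0.05), D = matrix(c(0.09, 0.01, 0.01, 0.004), 2, 2),
       sigma2 = 0.25, kappa = 8, lambda = exp(-8 * log(17) + 0.8 * (-6)),
       alpha = alpha)
}

# Dense-grid numeric integral of the joint likelihood for one subject:
# brute-force oracle over a (b0, b1) grid, independent of the package's
# quadrature path.
grid_joint_lik_subject <- function(theta, times, values, T_i, delta_i,
                                   lim = 6, ngrid = 201) {
  sd0 <- sqrt(theta$D[1, 1]); sd1 <- sqrt(theta$D[2, 2])
  b0g <- seq(-lim * sd0, lim * sd0, length.out = ngrid)
  b1g <- seq(-lim * sd1, lim * sd1, length.out = ngrid)
  Dinv <- solve(theta$D)
  logdetD <- determinant(theta$D)$modulus
  f <- outer(b0g, b1g, Vectorize(function(b0, b1) {
    m <- theta$beta[1] + b0 + (theta$beta[2] + b1) * times
    ll_y <- sum(stats::dnorm(values, m, sqrt(theta$sigma2), log = TRUE))
    haz <- function(u) theta$kappa * theta$lambda * u^(theta$kappa - 1) *
      exp(theta$alpha * (theta$beta[1] + b0 + (theta$beta[2] + b1) * u))
    Lam <- stats::integrate(haz, 0, T_i, rel.tol = 1e-10)$value
    ll_s <- delta_i * log(haz(T_i)) - Lam
    b <- c(b0, b1)
    ll_b <- -0.5 * (2 * log(2 * pi) + logdetD + drop(t(b) %*% Dinv %*% b))
    exp(ll_y + ll_s + ll_b)
  }))
  log(sum(f) * diff(b0g)[1] * diff(b1g)[1])
}

# Brute-force Cox partial log-likelihood (Breslow-free: no ties expected).
brute_cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
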