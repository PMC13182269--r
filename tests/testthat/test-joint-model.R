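test_that("at alpha = 0 the joint likelihood separates exactly", {
  set.seed(4)
  for (k in 1:20) {
    cfg <- scenario_config(n_per_group = 5, n_visits = 3,
                           slope_coef = stats::runif(1, 0, 0.1),
                           resid_sd = stats::runif(1, 0.4, 1.5),
                           seed = 100 + k)
    d <- simulate_dataset(cfg)
    th <- list(beta = stats::rnorm(2, c(6, 0), c(0.5, 0.05)),
               D = {
                 a <- stats::runif(1, 0.01, 0.2)
                 b <- stats::runif(1, 0.001, 0.02)
                 r <- stats::runif(1, -0.5, 0.5)
                 matrix(c(a, r * sqrt(a * b), r * sqrt(a * b), b), 2, 2)
               },
               sigma2 = stats::runif(1, 0.1, 1), kappa = stats::runif(1, 0.5, 4),
               lambda = exp(stats::runif(1, -8, -2)), alpha = 0)
    sep <- lmm_loglik(list(beta = th$beta, D = th$D, sigma2 = th$sigma2), d) +
      jmscreen:::weibull_null_loglik(th$kappa, th$lambda,
                                     d$subjects$event_time,
                                     d$subjects$status)
    expect_equal(joint_loglik(th, d), sep, tolerance = 1e-6)
  }
})

test_that("kappa = 1, alpha = 0 reduces to the censored exponential loglik", {
  d <- simulate_dataset(scenario_config(n_per_group = 10, seed = 2))
  th <- ref_theta(0); th$kappa <- 1; th$lambda <- 0.03
  T <- d$subjects$event_time; delta <- d$subjects$status
  expo <- sum(delta * log(0.03) - 0.03 * T)
  ll_lmm <- lmm_loglik(list(beta = th$beta, D = th$D, sigma2 = th$sigma2), d)
  expect_equal(joint_loglik(th, d), ll_lmm + expo, tolerance = 1e-8)
})

test_that("joint likelihood matches Monte-Carlo and dense-grid oracles", {
  # two subjects, two visits each, alpha != 0
  m <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                  time = c(0, 4, 0, 4), feature_id = "f",
                  value = c(6.2, 6.6, 5.7, 5.5))
  s <- data.frame(subject_id = c("a", "b"), event_time = c(12, 16),
                  status = c(1L, 0L), group = c("case", "control"))
  d <- longitudinal_dataset(m, s)
  th <- ref_theta(alpha = 0.6)

  ll <- joint_loglik(th, d, joint_model_spec(n_gh = 15, n_gl = 25))

  # dense-grid oracle (independent numeric double integral)
  oracle_grid <- grid_joint_lik_subject(th, c(0, 4), c(6.2, 6.6), 12, 1) +
    grid_joint_lik_subject(th, c(0, 4), c(5.7, 5.5), 16, 0)
  expect_equal(ll, oracle_grid, tolerance = 1e-5)

  # Monte-Carlo oracle with 1e6 prior draws per subject
  set.seed(77)
  mc_subject <- function(times, values, T_i, delta_i, n_mc = 1e6) {
    ch <- t(chol(th$D))
    b <- ch %*% matrix(stats::rnorm(2 * n_mc), 2)
    a0 <- th$beta[1] + b[1, ]; a1 <- th$beta[2] + b[2, ]
    ll_y <- 0
    for (j in seq_along(times))
      ll_y <- ll_y + stats::dnorm(values[j], a0 + a1 * times[j],
                                  sqrt(th$sigma2), log = TRUE)
    gl <- gauss_legendre(40)
    u <- T_i * (gl$nodes + 1) / 2
    Lam <- 0
    for (j in seq_along(u))
      Lam <- Lam + gl$weights[j] * th$kappa * th$lambda *
        u[j]^(th$kappa - 1) * exp(th$alpha * (a0 + a1 * u[j]))
    Lam <- Lam * T_i / 2
    logh <- log(th$kappa * th$lambda) + (th$kappa - 1) * log(T_i) +
      th$alpha * (a0 + a1 * T_i)
    w <- ll_y + delta_i * logh - Lam
    mx <- max(w)
    est <- mx + log(mean(exp(w - mx)))
    se <- stats::sd(exp(w - mx)) / sqrt(n_mc) / mean(exp(w - mx))
    c(est = est, se = se)
  }
  mc_a <- mc_subject(c(0, 4), c(6.2, 6.6), 12, 1)
  mc_b <- mc_subject(c(0, 4), c(5.7, 5.5), 16, 0)
  mc_se <- sqrt(mc_a["se"]^2 + mc_b["se"]^2)
  expect_lt(abs(ll - (mc_a["est"] + mc_b["est"])), 3 * mc_se)
})

test_that("quadrature is converged at the default 9 nodes", {
  d <- simulate_dataset(scenario_config(n_per_group = 25, slope_coef = 0.05,
                                        seed = 31))
  th <- ref_theta(alpha = 0.5)
  ll9 <- joint_loglik(th, d, joint_model_spec(n_gh = 9))
  ll15 <- joint_loglik(th, d, joint_model_spec(n_gh = 15))
  expect_lt(abs(ll9 - ll15), 1e-4)
})

test_that("parameters are recovered within 3 SE from joint-law data", {
  theta <- ref_theta(alpha = 0.8)
  d <- simulate_joint_data(theta, 500, seed = 101)
  expect_gt(sum(d$subjects$status), 50)
  fit <- fit_joint_model(d)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_start - 1e-8)  # monotone improvement

  truth <- jmscreen:::.jm_pack(theta)
  est <- fit$par
  for (i in c(1, 2, 6, 7, 8, 9)) {   # beta, log s2, log kappa/lambda, alpha
    expect_lt(abs(est[i] - truth[i]), 3 * fit$se[i])
  }
  # association recovered and clearly nonzero
  expect_lt(abs(fit$theta$alpha - 0.8), 3 * fit$se[["alpha"]])
  expect_lt(wald_test(fit)$p, 0.01)
})

test_that("degenerate/edge cases behave as documented", {
  d <- simulate_dataset(scenario_config(n_per_group = 10, seed = 6))
  # no events -> refusal
  d0 <- d; d0$subjects$status <- 0L
  expect_error(fit_joint_model(d0), "no observed events")
  # too few subjects
  keep <- d$subjects$subject_id[1:3]
  d3 <- longitudinal_dataset(
    d$measurements[d$measurements$subject_id %in% keep, ],
    d$subjects[d$subjects$subject_id %in% keep, ], validate = FALSE)
  expect_error(fit_joint_model(d3), "at least 5 subjects")
})

test_that("wald_test follows the normal reference distribution", {
  fit <- structure(list(theta = list(alpha = 0), se = c(alpha = 0.5),
                        converged = TRUE), class = "joint_model_fit")
  expect_equal(wald_test(fit)$p, 1)
  fit$theta$alpha <- 1.959964 * 0.5
  expect_equal(wald_test(fit)$p, 0.05, tolerance = 1e-6)
  fit$converged <- FALSE
  expect_false(wald_test(fit)$defined)
  expect_true(is.na(wald_test(fit)$p))
})

test_that("conditional survival matches closed forms and a dense grid", {
  theta <- ref_theta(alpha = 0.4)
  d <- simulate_joint_data(theta, 30, seed = 3)
  fit <- fit_joint_model(d, control = list(compute_se = FALSE,
                                           check_gradient = FALSE))
  b <- c(0.2, -0.01)
  expect_equal(conditional_survival(fit, b, 5, 5), 1)
  expect_error(conditional_survival(fit, b, 5, 4), "t >= s")

  # alpha = 0, kappa = 1: exponential closed form
  fit0 <- fit
  fit0$theta <- list(beta = c(6, 0), D = theta$D, sigma2 = 0.2,
                     kappa = 1, lambda = 0.05, alpha = 0)
  expect_equal(conditional_survival(fit0, b, 2, 7), exp(-0.05 * 5),
               tolerance = 1e-10)

  # general case vs fine trapezoid
  s <- 3; t <- 14
  u <- seq(s, t, length.out = 20001)
  th <- fit$theta
  h <- th$kappa * th$lambda * u^(th$kappa - 1) *
    exp(th$alpha * ((th$beta[1] + b[1]) + (th$beta[2] + b[2]) * u))
  trap <- exp(-sum((h[-1] + h[-length(h)]) / 2 * diff(u)))
  expect_equal(conditional_survival(fit, b, s, t), trap, tolerance = 1e-6)
  # non-increasing in t
  ts <- seq(s, t, length.out = 8)
  surv <- vapply(ts, function(x) conditional_survival(fit, b, s, x), 0)
  expect_true(all(diff(surv) <= 1e-12))
})
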