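test_that("noise-free linear data is fitted exactly", {
  m <- expand.grid(subject_id = c("a", "b", "c"), time = 0:4)
  m$feature_id <- "f"; m$value <- 2 + 0.5 * m$time
  s <- data.frame(subject_id = c("a", "b", "c"), event_time = 10,
                  status = 0L, group = "control")
  d <- longitudinal_dataset(m, s)
  fit <- suppressWarnings(fit_lmm(d))
  expect_equal(unname(fit$beta), c(2, 0.5), tolerance = 1e-5)
  expect_lt(fit$sigma2, 1e-6)
  expect_lt(max(abs(fit$D)), 1e-4)
})

test_that("degenerate designs are rejected", {
  m <- data.frame(subject_id = c("a", "b"), time = 1,
                  feature_id = "f", value = c(1, 3))
  s <- data.frame(subject_id = c("a", "b"), event_time = 5, status = 0L,
                  group = "control")
  expect_error(fit_lmm(longitudinal_dataset(m, s)), "identifiable")
})

test_that("ML estimates agree with lme4 and recover truth at n = 500", {
  skip_if_not_installed("lme4")
  theta <- ref_theta(alpha = 0)
  d <- simulate_joint_data(theta, 500, seed = 42)
  fit <- fit_lmm(d)
  lf <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ time + (time | subject_id), data = d$measurements,
               REML = FALSE)))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-3)

  # recovery within 3 SE (lme4's Wald SEs as the scale reference)
  se_beta <- sqrt(diag(as.matrix(stats::vcov(lf))))
  expect_lt(abs(fit$beta[1] - theta$beta[1]), 3 * se_beta[1])
  expect_lt(abs(fit$beta[2] - theta$beta[2]), 3 * se_beta[2])
  expect_equal(fit$sigma2, theta$sigma2, tolerance = 0.1)
  expect_equal(fit$D[1, 1], theta$D[1, 1], tolerance = 0.25)
})

test_that("lmm_loglik matches closed forms and a quadrature oracle", {
  # one subject, one observation, D = 0: a plain univariate normal density
  m <- data.frame(subject_id = "a", time = 2, feature_id = "f", value = 7)
  s <- data.frame(subject_id = "a", event_time = 5, status = 0L,
                  group = "control")
  d1 <- longitudinal_dataset(m, s)
  pars <- list(beta = c(6, 0.3), D = matrix(0, 2, 2), sigma2 = 0.5)
  expect_equal(lmm_loglik(pars, d1),
               stats::dnorm(7, 6 + 0.3 * 2, sqrt(0.5), log = TRUE),
               tolerance = 1e-12)

  # quadrature oracle on a 2-subject instance with full D
  d <- toy_dataset()
  pars <- list(beta = c(5, 0.2),
               D = matrix(c(0.4, 0.05, 0.05, 0.02), 2, 2), sigma2 = 0.3)
  gh <- gauss_hermite(40)
  ch <- t(chol(pars$D))
  oracle <- 0
  for (id in c("a", "b", "c")) {
    mi <- d$measurements[d$measurements$subject_id == id, ]
    dens <- 0
    for (i in seq_along(gh$nodes)) for (j in seq_along(gh$nodes)) {
      b <- sqrt(2) * ch %*% c(gh$nodes[i], gh$nodes[j])
      mu <- pars$beta[1] + b[1] + (pars$beta[2] + b[2]) * mi$time
      dens <- dens + gh$weights[i] * gh$weights[j] / pi *
        prod(stats::dnorm(mi$value, mu, sqrt(pars$sigma2)))
    }
    oracle <- oracle + log(dens)
  }
  expect_equal(lmm_loglik(pars, d), oracle, tolerance = 1e-6)

  # additivity: duplicating a subject doubles its contribution
  m2 <- d$measurements[d$measurements$subject_id == "a", ]
  m2$subject_id <- "a2"
  d2 <- longitudinal_dataset(
    rbind(d$measurements, m2),
    rbind(d$subjects, data.frame(subject_id = "a2", event_time = 6,
                                 status = 1L, group = "case")),
    validate = FALSE)
  d_a2 <- longitudinal_dataset(
    m2, data.frame(subject_id = "a2", event_time = 6, status = 1L,
                   group = "case"), validate = FALSE)
  ll_a <- lmm_loglik(pars, d_a2)
  expect_equal(lmm_loglik(pars, d2), lmm_loglik(pars, d) + ll_a,
               tolerance = 1e-10)

  # invariance to row order
  shuf <- d$measurements[sample(nrow(d$measurements)), ]
  expect_equal(lmm_loglik(pars, longitudinal_dataset(shuf, d$subjects)),
               lmm_loglik(pars, d), tolerance = 1e-10)

  expect_error(lmm_loglik(list(beta = c(0, 0),
                               D = matrix(c(1, 2, 2, 1), 2, 2), sigma2 = 1),
                          d), "positive semidefinite")
})

test_that("fitted loglik dominates the generating parameters", {
  theta <- ref_theta(alpha = 0)
  d <- simulate_joint_data(theta, 100, seed = 9)
  fit <- fit_lmm(d)
  ll_truth <- lmm_loglik(list(beta = theta$beta, D = theta$D,
                              sigma2 = theta$sigma2), d)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("BLUPs shrink towards zero and approach per-subject OLS", {
  fit <- list(beta = c(5, 0.1),
              D = matrix(c(0.5, 0, 0, 0.05), 2, 2), sigma2 = 0.2)
  expect_equal(predict_blup(fit, numeric(), numeric()), c(b0 = 0, b1 = 0))
  # shrinkage limit D -> 0
  fit0 <- fit; fit0$D <- matrix(c(1e-12, 0, 0, 1e-12), 2, 2)
  b <- predict_blup(fit0, c(0, 1, 2), c(9, 9.5, 10))
  expect_lt(max(abs(b)), 1e-8)

  # many low-noise observations (and matching small model sigma2):
  # BLUP approaches the per-subject OLS deviations
  set.seed(1)
  tt <- seq(0, 10, length.out = 80)
  yy <- (5 + 0.8) + (0.1 - 0.03) * tt + stats::rnorm(80, 0, 0.01)
  fit_lo <- fit; fit_lo$sigma2 <- 1e-4
  ols <- stats::lm.fit(cbind(1, tt), yy)$coefficients - fit$beta
  bl <- predict_blup(fit_lo, tt, yy)
  expect_equal(unname(bl), unname(ols), tolerance = 1e-3)

  # single-random-effect shrinkage bound: |BLUP| <= |OLS deviation|
  fit1 <- list(beta = c(5, 0), D = matrix(c(0.3, 0, 0, 1e-10), 2, 2),
               sigma2 = 0.5)
  for (k in 1:20) {
    y <- 5 + stats::rnorm(4, stats::rnorm(1, 0, 0.5), 0.7)
    dev <- mean(y) - 5
    expect_lte(abs(predict_blup(fit1, rep(0:3, 1) * 0, y)[["b0"]]),
               abs(dev) + 1e-10)
  }
})
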