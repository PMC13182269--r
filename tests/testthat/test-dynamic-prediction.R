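test_that("auroc matches hand-counted concordant pairs and edge cases", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auroc, 1.0)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auroc, 0.75)
  # ties counted half
  expect_equal(auroc(c(1, 1), c(0, 1))$auroc, 0.5)
  # one class absent -> undefined, flagged by NA
  expect_true(is.na(auroc(c(1, 2), c(1, 1))$auroc))
  # random scores: near 0.5, CI honest
  set.seed(2)
  a <- auroc(stats::runif(2000), rep(0:1, 1000))
  expect_between(a$auroc, 0.45, 0.55)
  expect_true(a$ci_low <= a$auroc && a$auroc <= a$ci_high)
})

test_that("auroc is invariant under strictly increasing transforms", {
  set.seed(5)
  sc <- stats::rnorm(60)
  lab <- rep(0:1, 30)
  base <- auroc(sc, lab)
  for (f in list(function(x) 2 * x + 3, exp, function(x) x^3)) {
    tr <- auroc(f(sc), lab)
    expect_equal(tr$auroc, base$auroc)
    expect_equal(tr$se, base$se)
  }
})

test_that("DeLong CI has near-nominal coverage under the null", {
  set.seed(11)
  cover <- replicate(200, {
    a <- auroc(stats::rnorm(60), rep(0:1, 30))
    a$ci_low <= 0.5 && 0.5 <= a$ci_high
  })
  # binomial 3 sigma around 0.95
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
})

test_that("compare_methods agrees with enumeration and permutation oracles", {
  expect_equal(compare_methods(1:6, 1:6), 1)
  # spec example: constant unit differences, n = 6 -> 2 * (1/64)
  a <- c(1, 2, 3, 4, 5, 6); b <- c(2, 3, 4, 5, 6, 7)
  expect_equal(compare_methods(a, b), 2 / 64, tolerance = 1e-12)
  # independent enumeration oracle for untied differences
  set.seed(3)
  d <- c(0.3, -0.1, 0.45, 0.2, 0.6, -0.05, 0.15)
  r <- rank(abs(d)); w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
  w_all <- as.vector(signs %*% r)
  p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(compare_methods(d + 1, rep(1, 7)), p_exact, tolerance = 1e-12)
  # matches a permutation oracle on random instances
  for (k in 1:5) {
    x <- stats::rnorm(9); y <- stats::rnorm(9)
    p_pkg <- compare_methods(x, y)
    dd <- x - y
    set.seed(100 + k)
    perm <- replicate(4000, {
      s <- sample(c(-1, 1), 9, replace = TRUE)
      abs(sum(rank(abs(dd)) * (s * dd > 0)) - sum(rank(abs(dd))) / 2)
    })
    obs <- abs(sum(rank(abs(dd)) * (dd > 0)) - sum(rank(abs(dd))) / 2)
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(p_pkg - p_perm), 0.035)
  }
})

test_that("dynamic risk is zero at t = s, monotone in t, constant at alpha 0", {
  theta <- ref_theta(alpha = 0.8)
  d <- simulate_joint_data(theta, 120, seed = 55)
  fit <- fit_joint_model(d, control = list(compute_se = FALSE,
                                           check_gradient = FALSE))
  expect_true(all(predict_dynamic_risk(fit, d, 5, 5)$risk == 0))
  expect_error(predict_dynamic_risk(fit, d, 5, 4), "t >= s")
  risks <- vapply(c(6, 8, 10, 14, 18),
                  function(t) predict_dynamic_risk(fit, d, 5, t)$risk,
                  numeric(120))
  expect_true(all(apply(risks, 1, diff) >= -1e-10))
  expect_true(all(risks >= 0 & risks <= 1))

  # alpha = 0: the marker carries no information; all at-risk subjects get
  # the same risk
  fit0 <- fit
  fit0$theta <- list(beta = c(6, 0), D = theta$D, sigma2 = 0.25,
                     kappa = 2, lambda = 1e-3, alpha = 0)
  r0 <- predict_dynamic_risk(fit0, d, 5, 15)$risk
  at_risk <- d$subjects$event_time > 5
  expect_lt(diff(range(r0[at_risk])), 1e-12)
})

test_that("dynamic risk matches a dense-grid posterior oracle", {
  theta <- ref_theta(alpha = 0.6)
  # near-1-D model: slope variance negligible -> grid over b0 only
  theta$D <- matrix(c(0.09, 0, 0, 1e-10), 2, 2)
  d <- simulate_joint_data(theta, 25, seed = 66)
  fit <- list(theta = theta, spec = joint_model_spec(n_gh = 15, n_gl = 25),
              converged = TRUE)
  class(fit) <- "joint_model_fit"
  s <- 8; t <- 16
  pk <- predict_dynamic_risk(fit, d, s, t)

  b0g <- seq(-6 * 0.3, 6 * 0.3, length.out = 4001)
  surv_b <- function(b0, upto, a1) {
    f <- function(u) theta$kappa * theta$lambda * u^(theta$kappa - 1) *
      exp(theta$alpha * (theta$beta[1] + b0 + a1 * u))
    exp(-stats::integrate(f, 0, upto, rel.tol = 1e-10)$value)
  }
  for (i in c(3, 11)) {
    mi <- d$measurements[d$measurements$subject_id ==
                           d$subjects$subject_id[i] &
                           d$measurements$time <= s, ]
    s_i <- min(s, d$subjects$event_time[i])
    post <- vapply(b0g, function(b0) {
      mu <- theta$beta[1] + b0 + theta$beta[2] * mi$time
      exp(sum(stats::dnorm(mi$value, mu, sqrt(theta$sigma2), log = TRUE)) +
            stats::dnorm(b0, 0, 0.3, log = TRUE))
    }, 0)
    St <- vapply(b0g, surv_b, 0, upto = t, a1 = theta$beta[2])
    Ss <- vapply(b0g, surv_b, 0, upto = s_i, a1 = theta$beta[2])
    oracle <- 1 - sum(post * St) / sum(post * Ss)
    expect_equal(pk$risk[i], oracle, tolerance = 1e-4)
  }
})

test_that("evaluate_scenario reports per-method, per-followup rows", {
  cfg <- scenario_config(n_per_group = 25, slope_coef = 0.1, resid_sd = 0.5,
                         seed = 71)
  pair <- simulate_scenario_pair(cfg)
  res <- suppressWarnings(
    evaluate_scenario(pair$train, pair$test, methods = c("pccox", "cox")))
  expect_equal(nrow(res), 6)
  expect_setequal(res$followup, c(5, 10, 15))
  expect_true(all(res$converged))
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
  expect_true(all(res$ci_low <= res$auroc & res$auroc <= res$ci_high))
  # strong signal at full follow-up: clearly informative
  expect_gt(res$auroc[res$method == "cox" & res$followup == 15], 0.8)
})
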