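# Two well-separated planted classes used in several blocks: class 1 rises
# and has early events, class 2 falls and has late events.
planted_two_class_data <- function(n = 100, seed = 12, slope = 0.5) {
  set.seed(seed)
  cls <- rep(1:2, each = n / 2)
  times <- seq(0, 10, length.out = 6)
  ml <- vector("list", n); Tv <- numeric(n); dv <- integer(n)
  for (i in seq_len(n)) {
    b0 <- stats::rnorm(1, 0, 0.2)
    sl <- if (cls[i] == 1) slope else -slope
    lam <- if (cls[i] == 1) 0.08 else 0.01
    tt <- stats::rexp(1, lam)
    Tv[i] <- min(tt, 20); dv[i] <- as.integer(tt <= 20)
    ml[[i]] <- data.frame(subject_id = sprintf("s%03d", i),
                          time = times, feature_id = "f",
                          value = 6 + b0 + sl * times +
                            stats::rnorm(6, 0, 0.4))
  }
  longitudinal_dataset(
    do.call(rbind, ml),
    data.frame(subject_id = sprintf("s%03d", seq_len(n)), event_time = Tv,
               status = dv, group = ifelse(cls == 1, "case", "control")),
    validate = FALSE)
}

test_that("ng = 1 reduces exactly to the separable LMM + Weibull fit", {
  d <- simulate_dataset(scenario_config(n_per_group = 15, seed = 14))
  f1 <- suppressWarnings(fit_jlcm(d, ng = 1))
  lmm0 <- suppressWarnings(fit_lmm(d))
  wb0 <- jmscreen:::.fit_weibull_null(d$subjects$event_time,
                                      d$subjects$status)
  expect_equal(f1$loglik,
               lmm0$loglik + jmscreen:::weibull_null_loglik(
                 wb0$kappa, wb0$lambda, d$subjects$event_time,
                 d$subjects$status),
               tolerance = 1e-6)
  expect_equal(f1$bic, -2 * f1$loglik + 8 * log(30), tolerance = 1e-10)
})

test_that("EM ascends and recovers well-separated classes", {
  d <- planted_two_class_data(n = 200, seed = 5)
  fit <- suppressWarnings(fit_jlcm(d, ng = 2))
  expect_true(fit$converged)
  # EM ascent, iteration by iteration
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # modal assignment accuracy > 95% (up to label switching)
  truth <- rep(1:2, each = 100)
  modal <- max.col(fit$posteriors)
  acc <- max(mean(modal == truth), mean(modal == 3 - truth))
  expect_gt(acc, 0.95)
  # posteriors are a proper stochastic matrix; pi a simplex
  expect_equal(rowSums(fit$posteriors), rep(1, 200), tolerance = 1e-9)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  expect_equal(sum(fit$class_sizes), 200)
})

test_that("the likelihood is symmetric under label permutation", {
  d <- planted_two_class_data(n = 60, seed = 9)
  fit <- suppressWarnings(fit_jlcm(d, ng = 2))
  st <- jmscreen:::.joint_stats(d)
  params <- list(pi = fit$pi, class_beta = fit$class_beta, D = fit$D,
                 sigma2 = fit$sigma2, kappa = fit$kappa, lambda = fit$lambda)
  swapped <- params
  swapped$pi <- rev(params$pi)
  swapped$class_beta <- params$class_beta[, 2:1]
  swapped$lambda <- rev(params$lambda)
  expect_equal(jmscreen:::.jlcm_loglik(params, st),
               jmscreen:::.jlcm_loglik(swapped, st), tolerance = 1e-10)
})

test_that("grid search dominates a single start and is deterministic", {
  d <- planted_two_class_data(n = 80, seed = 21)
  single <- suppressWarnings(fit_jlcm(d, ng = 2))
  grid <- suppressWarnings(grid_search_fit(d, ng = 2, n_starts = 6,
                                           seed = 3))
  expect_gte(grid$loglik, single$loglik - 1e-6)
  grid2 <- suppressWarnings(grid_search_fit(d, ng = 2, n_starts = 6,
                                            seed = 3))
  expect_equal(grid$loglik, grid2$loglik, tolerance = 1e-12)
  expect_equal(grid$pi, grid2$pi, tolerance = 1e-12)
  # n_starts = 1 is exactly the canonical start
  g1 <- suppressWarnings(grid_search_fit(d, ng = 2, n_starts = 1))
  expect_equal(g1$loglik, single$loglik, tolerance = 1e-12)
})

test_that("BIC selects two classes on strong mixtures, one on null data", {
  d2 <- planted_two_class_data(n = 120, seed = 33)
  sel <- suppressWarnings(select_ng(d2, candidates = 1:2, n_starts = 4,
                                    seed = 2))
  expect_equal(sel$ng, 2L)
  cand <- attr(sel, "candidates")
  expect_lt(cand[[2]]$bic, cand[[1]]$bic)

  # homogeneous data (single class in both components): ng = 1 wins in
  # most replicates
  th0 <- ref_theta(0)
  th0$lambda <- log(2) / 17^8   # alpha = 0: median event at 17 y
  picks <- vapply(1:8, function(k) {
    d0 <- simulate_joint_data(th0, 40, seed = 400 + k)
    suppressWarnings(select_ng(d0, candidates = 1:2, n_starts = 3,
                               seed = k))$ng
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.75)
})

test_that("class_risk_score matches the hand-computed mixture formula", {
  d <- planted_two_class_data(n = 60, seed = 9)
  fit <- suppressWarnings(fit_jlcm(d, ng = 2))
  s <- 5; t <- 15
  r <- class_risk_score(fit, d, s, t)
  expect_true(all(r$risk >= 0 & r$risk <= 1))
  # t = s gives zero risk
  expect_equal(class_risk_score(fit, d, s, s)$risk, rep(0, 60))
  expect_error(class_risk_score(fit, d, 5, 4), "t >= s")

  # brute-force mixture for one subject
  st <- jmscreen:::.joint_stats(
    longitudinal_dataset(d$measurements[d$measurements$time <= s, ],
                         d$subjects, d$features, validate = FALSE))
  i <- 7
  s_i <- min(s, d$subjects$event_time[i])
  lw <- vapply(1:2, function(g) {
    jmscreen:::.jlcm_long_logdens(fit$class_beta[, g], fit$D, fit$sigma2,
                                  lapply(st, function(x) x[i]))[1] -
      fit$lambda[g] * s_i^fit$kappa + log(fit$pi[g])
  }, 0)
  post <- exp(lw - max(lw)); post <- post / sum(post)
  oracle <- sum(post * (1 - exp(-fit$lambda * (t^fit$kappa - s_i^fit$kappa))))
  expect_equal(r$risk[i], oracle, tolerance = 1e-10)

  # degenerate posterior reduces to the single-class Weibull formula
  fit1 <- fit; fit1$pi <- c(1 - 1e-14, 1e-14)
  fit1$class_beta[, 2] <- c(100, 0)   # impossible class
  r1 <- class_risk_score(fit1, d, s, t)
  direct <- 1 - exp(-fit$lambda[1] *
                      (t^fit$kappa - pmin(s, d$subjects$event_time)^fit$kappa))
  expect_equal(r1$risk, direct, tolerance = 1e-8)
})

test_that("the minimum-class-size rule is assertable on class_sizes", {
  d <- planted_two_class_data(n = 40, seed = 44)
  fit <- suppressWarnings(fit_jlcm(d, ng = 2))
  expect_length(fit$class_sizes, 2)
  expect_identical(all(fit$class_sizes > 5), TRUE)
})
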