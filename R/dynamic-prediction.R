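# Dynamic risk prediction from a fitted joint model, and evaluation of
# competing methods by AUROC on an independent test set.

# Vectorised conditional risk for all subjects of `newdata`:
#   risk_i = 1 - E[ S(t | b) | y_i(<= s), T_i > s ]
#          = 1 - sum_k w_k S(t | b_ik) / sum_k w_k S(s_i | b_ik),
# with b_ik Gauss-Hermite nodes of the Gaussian posterior of b given the
# subject's measurements up to s (survival-to-s enters through the
# denominator weights).  s_i is min(s, subject's event time) so that
# already-diagnosed subjects in observational cohorts are still scorable
# from their pre-event history.
.jm_risk <- function(fit, st, s_i, t) {
  th <- fit$theta
  q2 <- ghq_normal2d(fit$spec$n_gh)
  gl <- gauss_legendre(fit$spec$n_gl)
  D <- th$D; s2 <- th$sigma2
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  Di11 <- D[2, 2] / detD; Di22 <- D[1, 1] / detD; Di12 <- -D[1, 2] / detD
  p11 <- Di11 + st$n / s2; p12 <- Di12 + st$St / s2; p22 <- Di22 + st$Stt / s2
  detP <- p11 * p22 - p12^2
  u1 <- (st$Sy - th$beta[1] * st$n - th$beta[2] * st$St) / s2
  u2 <- (st$Sty - th$beta[1] * st$St - th$beta[2] * st$Stt) / s2
  mu1 <- (p22 * u1 - p12 * u2) / detP
  mu2 <- (p11 * u2 - p12 * u1) / detP
  s11 <- p22 / detP; s12 <- -p12 / detP; s22 <- p11 / detP
  l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(pmax(s22 - l21^2, 1e-300))

  z1 <- q2$z[, 1]; z2 <- q2$z[, 2]
  A0 <- th$beta[1] + mu1 + outer(l11, z1)
  A1 <- th$beta[2] + mu2 + outer(l21, z1) + outer(l22, z2)
  Lam_t <- .jm_cumhaz(A0, A1, rep(t, length(mu1)), th$kappa, th$lambda,
                      th$alpha, gl)
  Lam_s <- .jm_cumhaz(A0, A1, s_i, th$kappa, th$lambda, th$alpha, gl)
  Lam_s[s_i <= 0] <- 0
  w <- rep(q2$w, each = length(mu1))
  num <- rowSums(matrix(w * exp(-Lam_t), nrow = length(mu1)))
  den <- rowSums(matrix(w * exp(-Lam_s), nrow = length(mu1)))
  pmin(pmax(1 - num / den, 0), 1)
}

#' Dynamic event-risk prediction from a joint model
#'
#' Conditional probability of an event by horizon `t` given the subject's
#' biomarker history up to time `s` and event-free survival to `s`,
#' integrating the random effects over their posterior by Gauss-Hermite
#' quadrature.  At association zero every subject receives the same
#' (population) risk.
#'
#' @param fit a [fit_joint_model()] result.
#' @param newdata a [longitudinal_dataset()] of subjects to score (only
#'   measurements with `time <= s` are used).
#' @param s years of history used (>= 0).
#' @param t horizon in years, `t >= s`.
#' @return data.frame with `subject_id`, `s`, `t`, `risk`, `method = "jm"`.
#' @export
predict_dynamic_risk <- function(fit, newdata, s, t) {
  if (t < s || s < 0) stop("require t >= s >= 0")
  used <- newdata$measurements[newdata$measurements$time <= s + 1e-12, ,
                               drop = FALSE]
  cut <- longitudinal_dataset(used, newdata$subjects, newdata$features,
                              validate = FALSE)
  st <- .joint_stats(cut)
  if (any(st$n == 0))
    warning(sum(st$n == 0), " subject(s) have no measurements by s = ", s,
            "; their risk uses the population prior")
  s_i <- pmin(s, newdata$subjects$event_time)
  risk <- if (t == s) rep(0, st$n_subjects) else .jm_risk(fit, st, s_i, t)
  data.frame(subject_id = st$ids, s = s, t = t, risk = risk, method = "jm")
}

#' AUROC with DeLong confidence interval
#'
#' Mann-Whitney estimate `P(score_case > score_control) + P(tie)/2` with the
#' DeLong variance and a normal-approximation 95% confidence interval.
#' Scores are event risks and are never auto-flipped: estimates below 0.5
#' are reported as such.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 (or logical/case-control factor) outcome labels;
#'   1 = case.
#' @param conf_level confidence level (default 0.95).
#' @return list with `auroc`, `ci_low`, `ci_high`, `se`, `n_cases`,
#'   `n_controls`.
#' @export
auroc <- function(scores, labels, conf_level = 0.95) {
  if (is.factor(labels) || is.character(labels))
    labels <- as.integer(as.character(labels) %in% c("1", "case", "TRUE"))
  labels <- as.integer(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0)
    return(list(auroc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                se = NA_real_, n_cases = m, n_controls = n))
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  est <- mean(cmp)
  v10 <- rowMeans(cmp)        # per-case placement values
  v01 <- colMeans(cmp)        # per-control placement values
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  if (!is.finite(se)) se <- 0
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auroc = est, ci_low = max(0, est - zq * se),
       ci_high = min(1, est + zq * se), se = se,
       n_cases = m, n_controls = n)
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired AUROC vectors (one pair per
#' scenario).  Zero differences are dropped.  The p-value is exact for
#' n <= 25 (via the signed-rank distribution when the absolute differences
#' are untied, or full enumeration of the 2^n sign assignments with
#' midrank-tied statistics when n <= 16); otherwise the normal approximation
#' with continuity correction is used.
#'
#' @param results_a,results_b paired numeric vectors of equal length >= 5.
#' @return two-sided p-value (1 when all differences are zero).
#' @export
compare_methods <- function(results_a, results_b) {
  stopifnot(length(results_a) == length(results_b), length(results_a) >= 5)
  d <- results_a - results_b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  tied <- any(duplicated(abs(d)))
  if (!tied && n <= 25)
    return(stats::wilcox.test(d, exact = TRUE)$p.value)
  if (tied && n <= 16) {
    # enumerate all sign assignments of the midranked |d|
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
    return(min(1, p))
  }
  suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                      correct = TRUE)$p.value)
}

# --- method adapters used by evaluate_scenario / screening -----------------

.fit_method <- function(method, train, config = NULL, seed = 1L) {
  switch(method,
    jm = fit_joint_model(train, control = list(compute_se = FALSE)),
    lcmm = select_ng(train, candidates = 1:2, seed = seed),
    pccox = {
      lmk <- config$landmarks %||% c(5, 10, 15)
      fit_pccox(build_landmark_data(train, lmk))
    },
    cox = fit_cox_last_value(train),
    stop("unknown method: ", method))
}

.predict_method <- function(method, fit, test, s, t) {
  switch(method,
    jm = predict_dynamic_risk(fit, test, s, t)$risk,
    lcmm = class_risk_score(fit, test, s, t)$risk,
    pccox = predict_cox_risk(fit, test, s, t),
    cox = predict_cox_risk(fit, test, s, t),
    stop("unknown method: ", method))
}

.method_converged <- function(fit) isTRUE(fit$converged %||% TRUE)

#' Evaluate methods on one scenario's train/test pair
#'
#' Fits each requested method on the full training data, then for each
#' follow-up length truncates the test histories at that length and scores
#' each subject's predicted risk of an event by the horizon; performance is
#' the AUROC of the risks against the test case/control labels.  A method
#' that fails to converge yields rows with missing AUROC and a reason code.
#'
#' @param train_data,test_data [longitudinal_dataset()]s from the same
#'   scenario.
#' @param methods subset of `c("jm", "lcmm", "pccox", "cox")`.
#' @param followups follow-up lengths in years (default `c(5, 10, 15)`).
#' @param horizon prediction horizon in years (default 20).
#' @param seed seed for methods with stochastic initialisation search.
#' @return data.frame, one row per (method, followup): `method`, `followup`,
#'   `auroc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`, `converged`,
#'   `reason`.
#' @export
evaluate_scenario <- function(train_data, test_data,
                              methods = c("jm", "lcmm", "pccox", "cox"),
                              followups = c(5, 10, 15), horizon = 20,
                              seed = 1L) {
  rows <- list()
  labels <- as.integer(test_data$subjects$group == "case")
  for (method in methods) {
    fit <- try(.fit_method(method, train_data,
                           config = list(landmarks = followups), seed = seed),
               silent = TRUE)
    failed <- inherits(fit, "try-error")
    conv <- !failed && .method_converged(fit)
    for (f in followups) {
      row <- data.frame(method = method, followup = f, auroc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_cases = sum(labels), n_controls = sum(!labels),
                        converged = conv,
                        reason = if (failed) "fit_error" else
                          if (!conv) "non_convergence" else "")
      if (conv) {
        risk <- try(suppressWarnings(
          .predict_method(method, fit, test_data, f, horizon)), silent = TRUE)
        if (!inherits(risk, "try-error")) {
          a <- auroc(risk, labels)
          row$auroc <- a$auroc; row$ci_low <- a$ci_low
          row$ci_high <- a$ci_high
          row$n_cases <- a$n_cases; row$n_controls <- a$n_controls
        } else row$reason <- "prediction_error"
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
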