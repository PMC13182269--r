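# Shared-random-effects joint model.  Longitudinal submodel: the
# random-intercept/random-slope LMM (see lmm.R).  Survival submodel: Weibull
# proportional hazards with current-value association,
#   h_i(t | b_i) = kappa * lambda * t^(kappa-1) * exp(alpha * m_i(t)),
#   m_i(t) = (beta0 + b_i0) + (beta1 + b_i1) * t.
# The marginal likelihood integrates the random effects out with adaptive
# Gauss-Hermite quadrature centred on the closed-form Gaussian posterior of
# b_i given the subject's longitudinal data:
#   p(y_i, T_i, d_i) = p(y_i) * Int p(T_i, d_i | b) p(b | y_i) db,
# so the quadrature only sees the smooth survival factor, and at alpha = 0
# the integral is exact (the survival factor is constant in b) -- the
# likelihood then separates into the LMM and a censored Weibull likelihood.

#' Joint model specification
#'
#' @param n_gh Gauss-Hermite nodes per random-effect dimension (>= 5;
#'   default 9, i.e. 81 bivariate nodes).
#' @param n_gl Gauss-Legendre nodes for cumulative-hazard integrals
#'   (default 15).
#' @return object of class `joint_model_spec`.
#' @export
joint_model_spec <- function(n_gh = 9, n_gl = 15) {
  stopifnot(n_gh >= 5, n_gl >= 5)
  structure(list(n_gh = as.integer(n_gh), n_gl = as.integer(n_gl)),
            class = "joint_model_spec")
}

# Per-subject statistics aligned with the subjects table (subjects without
# measurements get zero counts; their b-posterior is then the prior).
.joint_stats <- function(data) {
  s <- data$subjects
  m <- data$measurements
  sid <- factor(m$subject_id, levels = s$subject_id)
  agg <- function(x, f) {
    v <- tapply(x, sid, f)
    v[is.na(v)] <- 0
    as.vector(v)
  }
  list(ids = s$subject_id,
       n = agg(m$value, length), St = agg(m$time, sum),
       Stt = agg(m$time^2, sum), Sy = agg(m$value, sum),
       Sty = agg(m$time * m$value, sum), Syy = agg(m$value^2, sum),
       T = s$event_time, delta = s$status,
       n_obs = nrow(m), n_subjects = nrow(s))
}

# Working parameter vector (all unconstrained):
#   beta0, beta1, l1, l2, l3 (log-Cholesky of D), log_sigma2,
#   log_kappa, log_lambda, alpha.
.jm_unpack <- function(par) {
  par <- unname(par)
  L <- matrix(c(exp(par[3]), par[4], 0, exp(par[5])), 2, 2)
  list(beta = par[1:2], D = L %*% t(L), sigma2 = exp(par[6]),
       kappa = exp(par[7]), lambda = exp(par[8]), alpha = par[9])
}

.jm_pack <- function(theta) {
  ch <- t(chol(theta$D))
  c(theta$beta, log(ch[1, 1]), ch[2, 1], log(ch[2, 2]), log(theta$sigma2),
    log(theta$kappa), log(theta$lambda), theta$alpha)
}

# n x K matrix of cumulative hazards Lambda_i(T_i | b_ik) for node-wise
# subject trajectories with intercepts A0 (n x K) and slopes A1 (n x K).
# Substituting v = (u/T)^kappa absorbs the Weibull kernel:
#   Lambda = lambda T^kappa Int_0^1 exp(alpha m(T v^(1/kappa))) dv,
# so the rule is exact at alpha = 0 and never sees the u^(kappa-1)
# singularity.
.jm_cumhaz <- function(A0, A1, Tv, kappa, lambda, alpha, gl) {
  acc <- 0
  for (j in seq_along(gl$nodes)) {
    v <- (gl$nodes[j] + 1) / 2
    u <- Tv * v^(1 / kappa)                  # length n, recycles down columns
    acc <- acc + (gl$weights[j] / 2) * exp(alpha * (A0 + A1 * u))
  }
  lambda * Tv^kappa * acc
}

# Negative joint log-likelihood on the working scale; vectorised over
# subjects and quadrature nodes.
.jm_nll <- function(par, st, q2, gl) {
  p <- .jm_unpack(par)
  if (any(!is.finite(unlist(p)))) return(1e10)
  D <- p$D; s2 <- p$sigma2
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  if (detD <= 0 || s2 <= 0) return(1e10)
  Di11 <- D[2, 2] / detD; Di22 <- D[1, 1] / detD; Di12 <- -D[1, 2] / detD

  p11 <- Di11 + st$n / s2
  p12 <- Di12 + st$St / s2
  p22 <- Di22 + st$Stt / s2
  detP <- p11 * p22 - p12^2
  if (any(!is.finite(detP) | detP <= 0)) return(1e10)
  u1 <- st$Sy - p$beta[1] * st$n - p$beta[2] * st$St
  u2 <- st$Sty - p$beta[1] * st$St - p$beta[2] * st$Stt
  rr <- st$Syy - 2 * p$beta[1] * st$Sy - 2 * p$beta[2] * st$Sty +
    p$beta[1]^2 * st$n + 2 * p$beta[1] * p$beta[2] * st$St +
    p$beta[2]^2 * st$Stt
  quad <- (rr - (p22 * u1^2 - 2 * p12 * u1 * u2 + p11 * u2^2) / (detP * s2)) / s2
  ll_long <- -0.5 * sum(st$n * log(2 * pi) + log(detP) + log(detD) +
                          st$n * log(s2) + quad)

  # posterior moments of b_i given y_i (prior when the subject has no data)
  mu1 <- (p22 * (u1 / s2) - p12 * (u2 / s2)) / detP
  mu2 <- (p11 * (u2 / s2) - p12 * (u1 / s2)) / detP
  s11 <- p22 / detP; s12 <- -p12 / detP; s22 <- p11 / detP
  l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(pmax(s22 - l21^2, 1e-300))

  z1 <- q2$z[, 1]; z2 <- q2$z[, 2]           # K standard-normal nodes
  A0 <- p$beta[1] + outer(mu1, rep(1, length(z1))) + outer(l11, z1)
  A1 <- p$beta[2] + outer(mu2, rep(1, length(z1))) +
    outer(l21, z1) + outer(l22, z2)

  Lam <- .jm_cumhaz(A0, A1, st$T, p$kappa, p$lambda, p$alpha, gl)
  logh <- log(p$kappa) + log(p$lambda) + (p$kappa - 1) * log(st$T) +
    p$alpha * (A0 + A1 * st$T)
  M <- st$delta * logh - Lam
  ll_surv <- sum(row_logsumexp(M + rep(log(q2$w), each = length(st$T))))
  nll <- -(ll_long + ll_surv)
  if (!is.finite(nll)) 1e10 else nll
}

#' Joint log-likelihood at given parameters
#'
#' Evaluates the marginal joint log-likelihood (random effects integrated
#' out) at natural-scale parameters.
#'
#' @param theta list with `beta` (length 2), `D` (2x2 PD), `sigma2`, `kappa`,
#'   `lambda` (all > 0) and `alpha`.
#' @param data a single-feature [longitudinal_dataset()].
#' @param spec a [joint_model_spec()].
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(theta, data, spec = joint_model_spec()) {
  stopifnot(theta$sigma2 > 0, theta$kappa > 0, theta$lambda > 0)
  st <- .joint_stats(data)
  val <- -.jm_nll(.jm_pack(theta), st, ghq_normal2d(spec$n_gh),
                  gauss_legendre(spec$n_gl))
  if (val <= -1e9)
    stop("non-finite joint likelihood integrand; check parameters/data")
  val
}

# Censored Weibull ML fit (no association), used for initialisation and for
# the separability identity:  loglik = sum d_i log(k l T^(k-1) k?) ...
#   log h0(T) = log k + log l + (k-1) log T;  Cumulative H0(T) = l T^k.
.fit_weibull_null <- function(T, delta) {
  if (sum(delta) == 0) {
    # no events: the rate MLE is at the zero boundary
    lam <- 1e-10
    return(list(kappa = 1, lambda = lam, loglik = -lam * sum(T),
                converged = TRUE))
  }
  nll <- function(par) {
    k <- exp(par[1]); l <- exp(par[2])
    v <- -sum(delta * (par[1] + par[2] + (k - 1) * log(T)) - l * T^k)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(c(0, log(sum(delta) / sum(T))), nll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  list(kappa = exp(opt$par[1]), lambda = exp(opt$par[2]),
       loglik = -opt$value, converged = opt$convergence == 0)
}

weibull_null_loglik <- function(kappa, lambda, T, delta) {
  sum(delta * (log(kappa) + log(lambda) + (kappa - 1) * log(T)) -
        lambda * T^kappa)
}

#' Fit the shared-random-effects joint model by maximum likelihood
#'
#' Initialised from the standalone LMM fit plus a null censored-Weibull fit
#' (association started at 0), then optimised by BFGS on the full working
#' parameter vector.  Non-convergence is reported in the `converged` flag of
#' the returned fit, not raised as an error.
#'
#' @param data a single-feature [longitudinal_dataset()] with >= 5 subjects
#'   and >= 1 observed event.
#' @param spec a [joint_model_spec()].
#' @param control list: `reltol` (1e-10), `maxit` (500), `compute_se`
#'   (TRUE; numerical observed-information standard errors),
#'   `check_gradient` (TRUE; gradient infinity-norm < `grad_tol` = 1e-3
#'   required for `converged`).
#' @return object of class `joint_model_fit` with elements `theta`
#'   (natural-scale parameter list), `par` (working vector), `se` (working
#'   scale; `se["alpha"]` is the association SE), `vcov`, `loglik`,
#'   `converged`, `n_subjects`, `spec`, and the data statistics needed for
#'   prediction.
#' @export
fit_joint_model <- function(data, spec = joint_model_spec(), control = list()) {
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 500,
                                 compute_se = TRUE, check_gradient = TRUE,
                                 grad_tol = 1e-3), control)
  st <- .joint_stats(data)
  if (st$n_subjects < 5) stop("need at least 5 subjects")
  if (sum(st$delta) < 1)
    stop("no observed events: the association is not estimable")
  q2 <- ghq_normal2d(spec$n_gh)
  gl <- gauss_legendre(spec$n_gl)

  lmm0 <- fit_lmm(data)
  wb0 <- .fit_weibull_null(st$T, st$delta)
  start <- c(lmm0$theta[1:5], lmm0$theta[6],
             log(wb0$kappa), log(wb0$lambda), 0)
  nll0 <- .jm_nll(start, st, q2, gl)

  opt <- stats::optim(start, .jm_nll, st = st, q2 = q2, gl = gl,
                      method = "BFGS",
                      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit,
                                     ndeps = rep(1e-6, 9)))
  converged <- opt$convergence == 0 && opt$value < nll0 + 1e-6
  if (ctrl$check_gradient && converged) {
    h <- 1e-5
    g <- vapply(1:9, function(i) {
      e <- rep(0, 9); e[i] <- h
      (.jm_nll(opt$par + e, st, q2, gl) -
         .jm_nll(opt$par - e, st, q2, gl)) / (2 * h)
    }, 0)
    converged <- max(abs(g)) < ctrl$grad_tol * max(1, abs(opt$value))
  }

  se <- rep(NA_real_, 9); V <- NULL
  if (ctrl$compute_se) {
    H <- try(num_hessian(function(x) .jm_nll(x, st, q2, gl), opt$par,
                         eps = 1e-4), silent = TRUE)
    if (!inherits(H, "try-error") && all(is.finite(H))) {
      V <- try(solve(H), silent = TRUE)
      if (inherits(V, "try-error") || any(!is.finite(diag(V))) ||
          any(diag(V) <= 0)) {
        warning("ill-conditioned observed information; using pseudo-inverse")
        e <- eigen(H, symmetric = TRUE)
        pos <- e$values > max(e$values) * 1e-10
        V <- e$vectors[, pos, drop = FALSE] %*%
          (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
      }
      se <- sqrt(pmax(diag(V), 0))
    }
  }
  names(se) <- c("beta0", "beta1", "l1", "l2", "l3", "log_sigma2",
                 "log_kappa", "log_lambda", "alpha")
  theta <- .jm_unpack(opt$par)
  structure(list(theta = theta, par = opt$par, se = se, vcov = V,
                 loglik = -opt$value, loglik_start = -nll0,
                 converged = converged, n_subjects = st$n_subjects,
                 n_events = sum(st$delta), spec = spec, stats = st),
            class = "joint_model_fit")
}

#' @export
print.joint_model_fit <- function(x, ...) {
  cat("Shared-random-effects joint model (Weibull baseline, current-value",
      "association)\n")
  cat("  ", x$n_subjects, " subjects, ", x$n_events, " events;  logLik ",
      format(x$loglik, digits = 8), ";  converged: ", x$converged,
      "\n", sep = "")
  cat("  longitudinal: intercept ", format(x$theta$beta[1], digits = 4),
      ", slope ", format(x$theta$beta[2], digits = 4),
      ", sigma ", format(sqrt(x$theta$sigma2), digits = 4), "\n", sep = "")
  cat("  baseline: kappa ", format(x$theta$kappa, digits = 4),
      ", lambda ", format(x$theta$lambda, digits = 4), "\n", sep = "")
  cat("  association alpha ", format(x$theta$alpha, digits = 4),
      " (se ", format(x$se[["alpha"]], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Wald test of the longitudinal-survival association
#'
#' @param fit a converged [fit_joint_model()] result.
#' @return list with `z`, `p` (two-sided normal), `alpha`, `se`.  For a
#'   non-converged fit both are `NA` and `defined` is `FALSE`.
#' @export
wald_test <- function(fit) {
  se <- fit$se[["alpha"]]
  if (!isTRUE(fit$converged) || !is.finite(se) || se <= 0)
    return(list(z = NA_real_, p = NA_real_, alpha = fit$theta$alpha,
                se = se, defined = FALSE))
  z <- fit$theta$alpha / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), alpha = fit$theta$alpha,
       se = se, defined = TRUE)
}

#' Conditional survival probability given random effects
#'
#' `S(t | b) / S(s | b) = exp(-Int_s^t h(u | b) du)` under the fitted Weibull
#' current-value hazard.
#'
#' @param fit a [fit_joint_model()] result.
#' @param b length-2 random-effect vector `(b0, b1)`.
#' @param s,t years with `t >= s >= 0`.
#' @return probability in (0, 1\]; equals 1 at `t == s`.
#' @export
conditional_survival <- function(fit, b, s, t) {
  if (t < s || s < 0) stop("require t >= s >= 0")
  if (t == s) return(1)
  th <- fit$theta
  gl <- gauss_legendre(fit$spec$n_gl)
  # substitute w = u^kappa, linear in the baseline cumulative hazard
  w <- s^th$kappa + (gl$nodes + 1) / 2 * (t^th$kappa - s^th$kappa)
  u <- w^(1 / th$kappa)
  m <- (th$beta[1] + b[1]) + (th$beta[2] + b[2]) * u
  H <- th$lambda * (t^th$kappa - s^th$kappa) *
    sum(gl$weights / 2 * exp(th$alpha * m))
  exp(-H)
}
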