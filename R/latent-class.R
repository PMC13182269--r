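# Joint latent-class mixed model: G latent subgroups with class-specific
# linear fixed effects and class-specific Weibull hazards under a
# proportional-hazards constraint (shared shape kappa, class-specific rate
# lambda_g); random effects (b0, b1) ~ N(0, D) and residual variance are
# shared across classes, and conditional on class the longitudinal and
# survival processes are independent, so the per-subject likelihood
#   L_i = sum_g pi_g * MVN(y_i; X beta_g, Z D Z' + s2 I)
#               * h_g(T_i)^d_i exp(-lambda_g T_i^kappa)
# is available in closed form.  Estimation is by EM; class number by BIC.

# Per-subject longitudinal log-density under class-g fixed effects,
# vectorised via the same Woodbury sufficient-statistic formulas as the LMM.
.jlcm_long_logdens <- function(beta, D, s2, st) {
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  Di11 <- D[2, 2] / detD; Di22 <- D[1, 1] / detD; Di12 <- -D[1, 2] / detD
  p11 <- Di11 + st$n / s2; p12 <- Di12 + st$St / s2; p22 <- Di22 + st$Stt / s2
  detP <- p11 * p22 - p12^2
  u1 <- st$Sy - beta[1] * st$n - beta[2] * st$St
  u2 <- st$Sty - beta[1] * st$St - beta[2] * st$Stt
  rr <- st$Syy - 2 * beta[1] * st$Sy - 2 * beta[2] * st$Sty +
    beta[1]^2 * st$n + 2 * beta[1] * beta[2] * st$St + beta[2]^2 * st$Stt
  quad <- (rr - (p22 * u1^2 - 2 * p12 * u1 * u2 + p11 * u2^2) / (detP * s2)) / s2
  -0.5 * (st$n * log(2 * pi) + log(detP) + log(detD) + st$n * log(s2) + quad)
}

.jlcm_surv_logdens <- function(kappa, lambda_g, st) {
  st$delta * (log(kappa) + log(lambda_g) + (kappa - 1) * log(st$T)) -
    lambda_g * st$T^kappa
}

# n x G matrix of complete per-class log joint densities (without log pi).
.jlcm_logdens <- function(params, st) {
  G <- length(params$pi)
  sapply(seq_len(G), function(g) {
    .jlcm_long_logdens(params$class_beta[, g], params$D, params$sigma2, st) +
      .jlcm_surv_logdens(params$kappa, params$lambda[g], st)
  })
}

.jlcm_loglik <- function(params, st) {
  ld <- .jlcm_logdens(params, st)
  sum(row_logsumexp(ld + rep(log(params$pi), each = st$n_subjects)))
}

.jlcm_n_params <- function(G) (G - 1) + 2 * G + 3 + 1 + 1 + G

#' Fit the joint latent-class mixed model by EM
#'
#' E-step: posterior class probabilities from the product of longitudinal
#' and survival contributions.  M-step: closed-form mixing proportions,
#' quasi-Newton update of the weighted longitudinal parameters
#' (class-specific intercept/slope, shared `D` and `sigma2`), and
#' profile update of the Weibull parameters (class rates in closed form
#' given the shared shape, shape by 1-D optimisation).  `ng = 1` reduces
#' exactly to the separable LMM + censored-Weibull maximum likelihood fit.
#'
#' @param data a single-feature [longitudinal_dataset()].
#' @param ng number of latent classes (1 or 2).
#' @param start optional start: list with `pi`, `class_beta` (2 x ng),
#'   `D`, `sigma2`, `kappa`, `lambda` (length ng).
#' @param control list: `max_iter` (200), `tol` (1e-8 relative loglik
#'   change), `min_pi` (1e-4; smaller mixing weight flags class collapse).
#' @return object of class `jlcm_fit`: `ng`, `pi`, `class_beta`, `D`,
#'   `sigma2`, `kappa`, `lambda`, `posteriors` (n x ng), `class_sizes`
#'   (modal assignment counts), `loglik`, `bic`, `converged`,
#'   `loglik_trace`.
#' @export
fit_jlcm <- function(data, ng = 2, start = NULL, control = list()) {
  ctrl <- utils::modifyList(list(max_iter = 200, tol = 1e-8, min_pi = 1e-4),
                            control)
  stopifnot(ng >= 1)
  st <- .joint_stats(data)
  n <- st$n_subjects

  if (ng == 1) {
    lmm0 <- fit_lmm(data)
    wb0 <- .fit_weibull_null(st$T, st$delta)
    ll <- lmm0$loglik + weibull_null_loglik(wb0$kappa, wb0$lambda, st$T,
                                            st$delta)
    return(structure(list(
      ng = 1L, pi = 1, class_beta = matrix(lmm0$beta, 2, 1),
      D = lmm0$D, sigma2 = lmm0$sigma2, kappa = wb0$kappa,
      lambda = wb0$lambda, posteriors = matrix(1, n, 1),
      class_sizes = n, loglik = ll,
      bic = -2 * ll + .jlcm_n_params(1) * log(n),
      converged = lmm0$converged && wb0$converged,
      loglik_trace = ll), class = "jlcm_fit"))
  }

  if (is.null(start)) start <- .jlcm_default_start(data, st, ng)
  params <- start
  ll_old <- .jlcm_loglik(params, st)
  trace <- ll_old
  converged <- FALSE; collapsed <- FALSE
  for (iter in seq_len(ctrl$max_iter)) {
    # E-step
    lw <- .jlcm_logdens(params, st) + rep(log(params$pi), each = n)
    w <- exp(lw - row_logsumexp(lw))
    # M-step
    params$pi <- pmax(colMeans(w), 1e-12)
    params$pi <- params$pi / sum(params$pi)
    if (any(params$pi < ctrl$min_pi)) { collapsed <- TRUE; break }
    params <- .jlcm_mstep_long(params, st, w)
    params <- .jlcm_mstep_surv(params, st, w)
    ll_new <- .jlcm_loglik(params, st)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < ctrl$tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- ll_new; break
    }
    ll_old <- ll_new
  }
  lw <- .jlcm_logdens(params, st) + rep(log(params$pi), each = n)
  post <- exp(lw - row_logsumexp(lw))
  modal <- max.col(post)
  structure(list(ng = as.integer(ng), pi = params$pi,
                 class_beta = params$class_beta, D = params$D,
                 sigma2 = params$sigma2, kappa = params$kappa,
                 lambda = params$lambda, posteriors = post,
                 class_sizes = tabulate(modal, ng), loglik = ll_old,
                 bic = -2 * ll_old + .jlcm_n_params(ng) * log(n),
                 converged = converged && !collapsed,
                 collapsed = collapsed, loglik_trace = trace),
            class = "jlcm_fit")
}

.jlcm_default_start <- function(data, st, ng) {
  lmm0 <- fit_lmm(data)
  wb0 <- .fit_weibull_null(st$T, st$delta)
  # split classes along the slope BLUPs (canonical deterministic start)
  spread <- stats::quantile(lmm0$blups$b1, c(0.25, 0.75))
  cb <- matrix(lmm0$beta, 2, ng)
  cb[2, ] <- lmm0$beta[2] + seq(spread[1], spread[2], length.out = ng)
  list(pi = rep(1 / ng, ng), class_beta = cb, D = lmm0$D,
       sigma2 = lmm0$sigma2, kappa = wb0$kappa,
       lambda = rep(wb0$lambda, ng) * seq(0.5, 2, length.out = ng))
}

# Weighted longitudinal M-step: BFGS on (beta_g, log-Cholesky D, log s2),
# warm-started at the current parameters.
.jlcm_mstep_long <- function(params, st, w) {
  G <- ncol(w)
  ch <- t(chol(params$D))
  par0 <- c(as.vector(params$class_beta),
            log(ch[1, 1]), ch[2, 1], log(ch[2, 2]), log(params$sigma2))
  obj <- function(par) {
    cb <- matrix(par[seq_len(2 * G)], 2, G)
    L <- matrix(c(exp(par[2 * G + 1]), par[2 * G + 2], 0,
                  exp(par[2 * G + 3])), 2, 2)
    D <- L %*% t(L); s2 <- exp(par[2 * G + 4])
    v <- -sum(vapply(seq_len(G), function(g)
      sum(w[, g] * .jlcm_long_logdens(cb[, g], D, s2, st)), 0))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(reltol = 1e-10, maxit = 200))
  G2 <- 2 * G
  L <- matrix(c(exp(opt$par[G2 + 1]), opt$par[G2 + 2], 0,
                exp(opt$par[G2 + 3])), 2, 2)
  params$class_beta <- matrix(opt$par[seq_len(G2)], 2, G)
  params$D <- L %*% t(L)
  params$sigma2 <- exp(opt$par[G2 + 4])
  params
}

# Weighted survival M-step: lambda_g closed form given kappa; kappa by 1-D
# profile optimisation.
.jlcm_mstep_surv <- function(params, st, w) {
  G <- ncol(w)
  prof <- function(log_k) {
    k <- exp(log_k)
    Tk <- st$T^k
    val <- 0
    for (g in seq_len(G)) {
      Ed <- sum(w[, g] * st$delta); ET <- sum(w[, g] * Tk)
      lam <- if (Ed > 0) Ed / ET else 1e-12
      val <- val + sum(w[, g] * (st$delta * (log_k + log(lam) +
                                               (k - 1) * log(st$T)) - lam * Tk))
    }
    val
  }
  opt <- stats::optimize(prof, c(log(0.05), log(50)), maximum = TRUE,
                         tol = 1e-8)
  k <- exp(opt$maximum); Tk <- st$T^k
  params$kappa <- k
  params$lambda <- vapply(seq_len(G), function(g) {
    Ed <- sum(w[, g] * st$delta)
    if (Ed > 0) Ed / sum(w[, g] * Tk) else 1e-12
  }, 0)
  params
}

#' @export
print.jlcm_fit <- function(x, ...) {
  cat("Joint latent-class mixed model, ng = ", x$ng, "\n", sep = "")
  cat("  pi:", paste(format(x$pi, digits = 3), collapse = ", "),
      " class sizes:", paste(x$class_sizes, collapse = "/"), "\n")
  cat("  logLik ", format(x$loglik, digits = 8), ";  BIC ",
      format(x$bic, digits = 8), ";  converged: ", x$converged, "\n",
      sep = "")
  invisible(x)
}

#' Multi-start grid search for the latent-class fit
#'
#' Runs [fit_jlcm()] from `n_starts` initialisations: the canonical start
#' derived from the one-class fit, plus Gaussian-jittered perturbations of
#' it (jitter scaled to parameter magnitudes).  Returns the converged fit
#' with the highest log-likelihood; if no start converges, the best
#' non-converged fit is returned with `converged = FALSE`.
#'
#' @inheritParams fit_jlcm
#' @param n_starts number of initialisations (>= 1, default 10).
#' @param seed seed for the jitter.
#' @return a `jlcm_fit`.
#' @export
grid_search_fit <- function(data, ng = 2, n_starts = 10, seed = 1L,
                            control = list()) {
  stopifnot(n_starts >= 1)
  if (ng == 1) return(fit_jlcm(data, ng = 1, control = control))
  st <- .joint_stats(data)
  base <- .jlcm_default_start(data, st, ng)
  best <- NULL; best_any <- NULL
  for (k in seq_len(n_starts)) {
    start <- base
    if (k > 1) {
      set.seed(substream_seed(seed, k))
      start$class_beta <- base$class_beta +
        matrix(stats::rnorm(2 * ng, 0, 1), 2, ng) *
        (abs(base$class_beta) * 0.2 + c(0.2, 0.05))
      start$lambda <- base$lambda * exp(stats::rnorm(ng, 0, 0.5))
      start$pi <- stats::runif(ng, 0.2, 0.8)
      start$pi <- start$pi / sum(start$pi)
    }
    fit <- try(fit_jlcm(data, ng = ng, start = start, control = control),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best_any) || fit$loglik > best_any$loglik) best_any <- fit
    if (fit$converged && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best) && is.null(best_any)) stop("all latent-class starts failed")
  best %||% best_any
}

#' Select the number of latent classes by BIC
#'
#' Fits each candidate class number with [grid_search_fit()] and returns the
#' fit with minimal BIC; ties go to the smaller class number.
#'
#' @inheritParams grid_search_fit
#' @param candidates class numbers to compare (default `1:2`).
#' @return the selected `jlcm_fit`; all candidate fits are attached as
#'   attribute `"candidates"`.
#' @export
select_ng <- function(data, candidates = 1:2, n_starts = 10, seed = 1L,
                      control = list()) {
  stopifnot(length(candidates) >= 1)
  fits <- lapply(sort(candidates), function(g)
    grid_search_fit(data, ng = g, n_starts = n_starts, seed = seed,
                    control = control))
  bics <- vapply(fits, function(f) f$bic, 0)
  best <- fits[[which.min(bics)]]   # which.min takes the first (smaller ng)
  attr(best, "candidates") <- fits
  best
}

#' Class-based dynamic risk score
#'
#' Posterior-weighted class-specific conditional event probability:
#' `sum_g P(class g | history to s, T > s) * (1 - S_g(t) / S_g(s))`, where
#' `S_g` is the class-g Weibull survival and the class posterior combines
#' the mixing proportions, the longitudinal density of the measurements up
#' to `s`, and survival to `s`.
#'
#' @param fit a `jlcm_fit`.
#' @param newdata a [longitudinal_dataset()] of subjects to score.
#' @param s years of history used; `t` horizon, `t >= s`.
#' @param t horizon in years.
#' @return data.frame with `subject_id`, `s`, `t`, `risk`,
#'   `method = "lcmm"`.
#' @export
class_risk_score <- function(fit, newdata, s, t) {
  if (t < s) stop("require t >= s")
  used <- newdata$measurements[newdata$measurements$time <= s + 1e-12, ,
                               drop = FALSE]
  cut <- longitudinal_dataset(used, newdata$subjects, newdata$features,
                              validate = FALSE)
  st <- .joint_stats(cut)
  if (t == s)
    return(data.frame(subject_id = st$ids, s = s, t = t, risk = 0,
                      method = "lcmm"))
  s_i <- pmin(s, newdata$subjects$event_time)
  G <- fit$ng
  lp <- sapply(seq_len(G), function(g) {
    .jlcm_long_logdens(fit$class_beta[, g], fit$D, fit$sigma2, st) -
      fit$lambda[g] * s_i^fit$kappa + log(fit$pi[g])
  })
  lp <- matrix(lp, nrow = st$n_subjects)
  post <- exp(lp - row_logsumexp(lp))
  risk <- rowSums(post * sapply(seq_len(G), function(g)
    1 - exp(-fit$lambda[g] * (t^fit$kappa - s_i^fit$kappa))))
  data.frame(subject_id = st$ids, s = s, t = t,
             risk = pmin(pmax(risk, 0), 1), method = "lcmm")
}
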