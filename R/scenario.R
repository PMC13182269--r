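# Simulation engine: benchmark scenario grid (single feature, two groups with
# opposite-sign slopes, late events) and a proteomics-like cohort generator
# with planted signal features for exercising the screening pipeline.

#' Scenario configuration for the benchmark simulator
#'
#' One cell of the simulation grid.  The default values describe the
#' reference scenario: 50 subjects per group observed at 10 evenly spaced
#' visits over 15 years, log-scale abundance centred at 6 with
#' random-intercept SD 0.1, residual SD 0.5, case slope `+slope_coef` and
#' control slope `-slope_coef`, and case events drawn from N(18, 1) truncated
#' to the interval (follow-up end, study end = 20].
#'
#' @param n_per_group subjects per group (>= 1).
#' @param n_visits follow-up time points per subject (>= 2).
#' @param followup_span length of the visit window in years.
#' @param slope_coef absolute abundance change per year (>= 0); cases get
#'   `+slope_coef`, controls `-slope_coef`.
#' @param resid_sd residual (measurement) SD on the abundance scale (> 0).
#' @param intercept_mean mean log-scale abundance.
#' @param rand_int_sd SD of the subject-level random intercept (>= 0).
#' @param event_mean,event_sd mean/SD (years) of the latent case event-time
#'   normal before truncation.
#' @param study_end administrative censoring horizon in years.
#' @param seed integer seed attached to the configuration.
#' @return object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(n_per_group = 50, n_visits = 10,
                            followup_span = 15, slope_coef = 0.05,
                            resid_sd = 0.5, intercept_mean = 6,
                            rand_int_sd = 0.1, event_mean = 18,
                            event_sd = 1, study_end = 20, seed = 1L) {
  cfg <- structure(list(n_per_group = n_per_group, n_visits = n_visits,
                        followup_span = followup_span, slope_coef = slope_coef,
                        resid_sd = resid_sd, intercept_mean = intercept_mean,
                        rand_int_sd = rand_int_sd, event_mean = event_mean,
                        event_sd = event_sd, study_end = study_end,
                        seed = as.integer(seed)),
                   class = "scenario_config")
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 1, cfg$n_visits >= 2,
            cfg$followup_span > 0, cfg$resid_sd > 0,
            cfg$rand_int_sd >= 0, cfg$slope_coef >= 0, cfg$event_sd > 0)
  if (!(cfg$followup_span < cfg$event_mean && cfg$event_mean < cfg$study_end))
    stop("require 0 < followup_span < event_mean < study_end")
  cfg
}

#' Build the benchmark scenario grid
#'
#' Cartesian product of variance levels, slope coefficients and group sizes,
#' enumerated deterministically with variance as the outermost loop, slope in
#' the middle and group size innermost.  The defaults reproduce the standard
#' 45-scenario grid: residual SD in \{0.5, 1, 1.5\}, slope in
#' \{0, 0.025, 0.05, 0.075, 0.1\}, group size in \{10, 50, 1000\}.
#'
#' @param variance_levels residual SDs (abundance units).
#' @param slope_levels absolute slope coefficients (abundance/year).
#' @param group_sizes subjects per group.
#' @param n_visits visits per subject (3 for the short-series variant).
#' @param base_seed seed of the first cell; cell i gets `base_seed + i - 1`.
#' @return list of [scenario_config()] objects, one per grid cell.
#' @export
#' @examples
#' length(build_scenario_grid())  # 45
build_scenario_grid <- function(variance_levels = c(0.5, 1.0, 1.5),
                                slope_levels = c(0, 0.025, 0.05, 0.075, 0.1),
                                group_sizes = c(10, 50, 1000),
                                n_visits = 10, base_seed = 1L) {
  if (!length(variance_levels) || !length(slope_levels) || !length(group_sizes))
    stop("all grid dimensions must be non-empty")
  grid <- expand.grid(size = group_sizes, slope = slope_levels,
                      variance = variance_levels,
                      KEEP.OUT.ATTRS = FALSE)  # size varies fastest
  lapply(seq_len(nrow(grid)), function(i) {
    scenario_config(n_per_group = grid$size[i], n_visits = n_visits,
                    slope_coef = grid$slope[i], resid_sd = grid$variance[i],
                    seed = base_seed + i - 1L)
  })
}

scenario_id <- function(cfg) {
  sprintf("var%g_slope%g_n%d_v%d", cfg$resid_sd, cfg$slope_coef,
          cfg$n_per_group, cfg$n_visits)
}

# Normal(mean, sd) truncated to (lo, hi] by rejection, preserving the
# smooth shape of the parent distribution (no atoms at the boundaries).
rtruncnorm_reject <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# Closed-form mean of the truncated normal, used as the simulator's
# event-time oracle in tests and in the acceptance report.
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Simulate one benchmark dataset
#'
#' Generates a single-feature two-group longitudinal dataset: each subject is
#' measured at `n_visits` evenly spaced times on \[0, `followup_span`\]
#' (both endpoints included); abundance is
#' `intercept_mean + b0 + sign * slope_coef * time + N(0, resid_sd^2)` with
#' subject random intercept `b0 ~ N(0, rand_int_sd^2)` and sign +1 for cases,
#' -1 for controls.  Case event times are drawn from
#' `N(event_mean, event_sd)` truncated by rejection to
#' `(followup_span, study_end]`; controls are administratively censored at
#' `study_end`.  Each subject consumes an independent substream derived from
#' the seed, so the same subject index always receives the same draws.
#'
#' @param config a [scenario_config()].
#' @param seed integer; overrides `config$seed` when given.
#' @return a [longitudinal_dataset()] with one feature `"marker"`.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  cfg <- validate_scenario_config(config)
  times <- seq(0, cfg$followup_span, length.out = cfg$n_visits)
  n <- 2L * cfg$n_per_group
  ids <- c(sprintf("case_%04d", seq_len(cfg$n_per_group)),
           sprintf("ctrl_%04d", seq_len(cfg$n_per_group)))
  grp <- rep(c("case", "control"), each = cfg$n_per_group)
  sgn <- ifelse(grp == "case", 1, -1)

  value <- matrix(NA_real_, n, cfg$n_visits)
  event_time <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    b0 <- stats::rnorm(1, 0, cfg$rand_int_sd)
    value[i, ] <- cfg$intercept_mean + b0 + sgn[i] * cfg$slope_coef * times +
      stats::rnorm(cfg$n_visits, 0, cfg$resid_sd)
    event_time[i] <- if (grp[i] == "case") {
      rtruncnorm_reject(1, cfg$event_mean, cfg$event_sd,
                        cfg$followup_span, cfg$study_end)
    } else cfg$study_end
  }

  measurements <- data.frame(
    subject_id = rep(ids, each = cfg$n_visits),
    time = rep(times, times = n),
    feature_id = "marker",
    value = as.vector(t(value)))
  subjects <- data.frame(subject_id = ids, event_time = event_time,
                         status = as.integer(grp == "case"), group = grp)
  features <- data.frame(feature_id = "marker",
                         n_peptides = NA_integer_, n_missing = 0L)
  out <- longitudinal_dataset(measurements, subjects, features,
                              validate = FALSE)
  attr(out, "config") <- cfg
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Draw case event times from the simulator's event-time law
#'
#' Normal(`event_mean`, `event_sd`) truncated by rejection to
#' `(followup_span, study_end]`, the law used for case events by
#' [simulate_dataset()].  The exact truncated-normal mean is available as
#' attribute `"exact_mean"`.
#'
#' @param n number of draws.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return numeric vector of `n` event times (years).
#' @export
simulate_case_event_times <- function(n, config = scenario_config(),
                                      seed = config$seed) {
  set.seed(seed)
  out <- rtruncnorm_reject(n, config$event_mean, config$event_sd,
                           config$followup_span, config$study_end)
  attr(out, "exact_mean") <- truncnorm_mean(config$event_mean, config$event_sd,
                                            config$followup_span,
                                            config$study_end)
  out
}

#' Simulate a single-feature dataset from the joint-model law
#'
#' Generates data exactly from the shared-random-effects joint model:
#' `(b0, b1) ~ N(0, D)`, measurements
#' `y = beta0 + b0 + (beta1 + b1) t + N(0, sigma2)` at the given visit
#' times, and event times by inverting the cumulative hazard of
#' `h(t) = kappa lambda t^(kappa-1) exp(alpha (beta0 + b0 + (beta1 + b1) t))`
#' at a unit exponential draw; administrative censoring at `cens_time`.
#' Measurements after the event are discarded (subjects keep at least their
#' pre-event visits).  Used for parameter-recovery and calibration checks.
#'
#' @param theta list with `beta`, `D`, `sigma2`, `kappa`, `lambda`, `alpha`.
#' @param n number of subjects.
#' @param times visit-time grid (years).
#' @param cens_time administrative censoring time (years).
#' @param seed integer seed.
#' @return a [longitudinal_dataset()]; true random effects in attribute
#'   `"ranef"`.
#' @export
simulate_joint_data <- function(theta, n, times = seq(0, 15, length.out = 10),
                                cens_time = 20, seed = 1L) {
  set.seed(seed)
  ch <- t(chol(theta$D))
  sid <- sprintf("s%04d", seq_len(n))
  b <- t(ch %*% matrix(stats::rnorm(2 * n), 2, n))
  ml <- vector("list", n); Tv <- numeric(n); dv <- integer(n)
  for (i in seq_len(n)) {
    a0 <- theta$beta[1] + b[i, 1]; a1 <- theta$beta[2] + b[i, 2]
    tt <- .cohort_draw_event(theta$kappa, theta$lambda, theta$alpha, a0, a1,
                             t_max = cens_time * 4)
    dv[i] <- as.integer(tt <= cens_time)
    Tv[i] <- min(tt, cens_time)
    keep <- times <= Tv[i]
    if (!any(keep)) keep <- seq_along(times) == 1  # keep baseline visit
    ml[[i]] <- data.frame(subject_id = sid[i], time = times[keep],
                          feature_id = "marker",
                          value = a0 + a1 * times[keep] +
                            stats::rnorm(sum(keep), 0, sqrt(theta$sigma2)))
  }
  subjects <- data.frame(subject_id = sid, event_time = Tv, status = dv,
                         group = ifelse(dv == 1, "case", "control"))
  out <- longitudinal_dataset(do.call(rbind, ml), subjects, validate = FALSE)
  attr(out, "ranef") <- b
  out
}

# Offset between the train seed and the paired independent test seed.
.test_seed_offset <- 100003L

#' Simulate a paired train/test dataset for one scenario
#'
#' The test set is an independent draw from the same generative law, using
#' `seed + 100003`.
#' @inheritParams simulate_dataset
#' @return list with elements `train` and `test`.
#' @export
simulate_scenario_pair <- function(config, seed = config$seed) {
  list(train = simulate_dataset(config, seed),
       test = simulate_dataset(config, seed + .test_seed_offset))
}

#' Truncate follow-up histories at a horizon
#'
#' Keeps only measurements with `time <= horizon`; the subjects and features
#' tables are unchanged.  Subjects left without any measurement are recorded
#' in the `"empty_subjects"` attribute and a warning is emitted; downstream
#' prediction code excludes them.
#'
#' @param data a [longitudinal_dataset()].
#' @param horizon years (> 0).
#' @return truncated [longitudinal_dataset()]; idempotent.
#' @export
truncate_followup <- function(data, horizon) {
  stopifnot(horizon > 0)
  m <- data$measurements
  keep <- m$time <= horizon + 1e-12
  out <- longitudinal_dataset(m[keep, , drop = FALSE], data$subjects,
                              data$features, validate = FALSE)
  empty <- setdiff(data$subjects$subject_id, out$measurements$subject_id)
  attr(out, "empty_subjects") <- empty
  if (length(empty))
    warning(length(empty), " subject(s) have no measurements before horizon ",
            horizon, " and are flagged for exclusion from prediction")
  out
}

# Latent-process cumulative hazard for the cohort generator:
# h(t) = kappa * lambda * t^(kappa-1) * exp(alpha * (b0 + b1 t)).
.cohort_cumhaz <- function(t, kappa, lambda, alpha, b0, b1, n_nodes = 25) {
  gl <- gauss_legendre(n_nodes)
  u <- t * ((gl$nodes + 1) / 2)^(1 / kappa)   # v = (u/t)^kappa substitution
  lambda * t^kappa * sum(gl$weights / 2 * exp(alpha * (b0 + b1 * u)))
}

.cohort_draw_event <- function(kappa, lambda, alpha, b0, b1, t_max = 60) {
  e <- stats::rexp(1)
  f <- function(t) .cohort_cumhaz(t, kappa, lambda, alpha, b0, b1) - e
  if (f(t_max) < 0) return(Inf)
  stats::uniroot(f, c(1e-6, t_max), tol = 1e-8)$root
}

#' Simulate a proteomics-like longitudinal cohort with planted features
#'
#' Emulates a small birth-cohort proteomics study: `n_cases + n_controls`
#' children sampled at fixed visit ages, a large feature panel of which
#' `n_assoc` features carry true association with the event process.  The
#' planted features are noisy readouts of a shared latent disease trajectory
#' `m(t) = b0 + b1 t`, and case onset ages are generated from the joint-model
#' law with hazard
#' `h(t) = kappa * lambda * t^(kappa - 1) * exp(alpha * m(t))`; subjects are
#' resampled until the case/control quotas are met (cases: event by
#' `study_end`; controls: event-free at `study_end`, administratively
#' censored there).  Null features are independent noise with subject random
#' intercepts and no event association.  Feature metadata (`n_peptides`,
#' `n_missing`) is randomised so that the peptide/missingness prefilter is
#' exercised; planted features always satisfy the default prefilter, and
#' `n_missing` measurements per feature are actually removed from the table.
#'
#' @param n_cases,n_controls group sizes (defaults 11 and 10).
#' @param n_features feature panel size (default 2000).
#' @param n_assoc number of planted associated features (default 5).
#' @param onset_mean target mean case onset age in years (default 11.7);
#'   calibrates the baseline Weibull scale so the median baseline onset age
#'   equals `onset_mean`.
#' @param visit_ages sampling ages in years (default 9 visits spanning
#'   0.8-14.4 years).
#' @param alpha association strength of planted features (default 1.5).
#' @param seed integer master seed.
#' @param intercept_mean,resid_sd abundance scale (defaults 6 and 0.5).
#' @return a [longitudinal_dataset()]; the planted feature ids are in
#'   attribute `"planted"` and the generating parameters in `"truth"`.
#' @export
simulate_cohort <- function(n_cases = 11, n_controls = 10, n_features = 2000,
                            n_assoc = 5, onset_mean = 11.7,
                            visit_ages = seq(0.8, 14.4, length.out = 9),
                            alpha = 1.5, seed = 1L,
                            intercept_mean = 6, resid_sd = 0.5) {
  stopifnot(n_assoc <= n_features, n_cases >= 1, n_controls >= 1)
  study_end <- max(visit_ages)
  kappa <- 8
  lambda <- log(2) / onset_mean^kappa  # baseline median onset = onset_mean
  b0_sd <- 0.3; b1_sd <- 0.06

  set.seed(substream_seed(seed, 0L))
  subj <- list(); n_case_got <- 0L; n_ctrl_got <- 0L; tries <- 0L
  while (n_case_got < n_cases || n_ctrl_got < n_controls) {
    tries <- tries + 1L
    if (tries > 100000L) stop("cohort rejection sampling failed to fill quotas")
    b0 <- stats::rnorm(1, 0, b0_sd); b1 <- stats::rnorm(1, 0, b1_sd)
    tt <- .cohort_draw_event(kappa, lambda, alpha, b0, b1)
    if (tt <= study_end && tt > min(visit_ages)) {
      if (n_case_got < n_cases) {
        n_case_got <- n_case_got + 1L
        subj[[length(subj) + 1L]] <- list(group = "case", event = tt,
                                          b0 = b0, b1 = b1)
      }
    } else if (tt > study_end && n_ctrl_got < n_controls) {
      n_ctrl_got <- n_ctrl_got + 1L
      subj[[length(subj) + 1L]] <- list(group = "control", event = study_end,
                                        b0 = b0, b1 = b1)
    }
  }
  grp <- vapply(subj, `[[`, "", "group")
  ord <- order(grp != "case")  # cases first, preserving draw order
  subj <- subj[ord]; grp <- grp[ord]
  n <- length(subj)
  ids <- sprintf("%s_%02d", ifelse(grp == "case", "case", "ctrl"),
                 stats::ave(seq_len(n), grp, FUN = seq_along))
  event_time <- vapply(subj, `[[`, 0, "event")
  subjects <- data.frame(subject_id = ids, event_time = event_time,
                         status = as.integer(grp == "case"), group = grp)

  planted <- if (n_assoc > 0) sprintf("prot_%04d", seq_len(n_assoc)) else character()
  fids <- sprintf("prot_%04d", seq_len(n_features))
  is_planted <- fids %in% planted
  set.seed(substream_seed(seed, 1L))
  n_peptides <- ifelse(is_planted, sample(6:30, n_features, replace = TRUE),
                       sample(1:30, n_features, replace = TRUE))
  n_missing <- ifelse(is_planted, sample(0:5, n_features, replace = TRUE),
                      sample(0:15, n_features, replace = TRUE))
  features <- data.frame(feature_id = fids, n_peptides = n_peptides,
                         n_missing = n_missing)

  # pre-event visit grid per subject (shared by all features)
  sub_times <- lapply(seq_len(n), function(i)
    visit_ages[visit_ages <= subjects$event_time[i] + 1e-9])
  sub_id_rep <- rep(ids, lengths(sub_times))
  sub_t_rep <- unlist(sub_times, use.names = FALSE)
  latent_rep <- unlist(lapply(seq_len(n), function(i)
    subj[[i]]$b0 + subj[[i]]$b1 * sub_times[[i]]), use.names = FALSE)
  rows <- vector("list", n_features)
  for (f in seq_len(n_features)) {
    set.seed(substream_seed(seed, 1000L + f))
    mu_f <- intercept_mean + stats::rnorm(1, 0, 0.5)
    traj <- if (is_planted[f]) latent_rep else
      rep(stats::rnorm(n, 0, 0.1), lengths(sub_times))  # null: subject shift
    ftab <- data.frame(subject_id = sub_id_rep, time = sub_t_rep,
                       feature_id = fids[f],
                       value = mu_f + traj +
                         stats::rnorm(length(sub_t_rep), 0, resid_sd))
    if (n_missing[f] > 0 && nrow(ftab) > n_missing[f])
      ftab <- ftab[-sample(nrow(ftab), n_missing[f]), , drop = FALSE]
    rows[[f]] <- ftab
  }
  out <- longitudinal_dataset(do.call(rbind, rows), subjects, features,
                              validate = FALSE)
  attr(out, "planted") <- planted
  attr(out, "truth") <- list(alpha = alpha, kappa = kappa, lambda = lambda,
                             b0_sd = b0_sd, b1_sd = b1_sd,
                             resid_sd = resid_sd, study_end = study_end)
  attr(out, "seed") <- as.integer(seed)
  out
}
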