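# Non-joint comparators: partly conditional Cox regression on
# landmark-stacked data and the conventional last-value Cox model.
# Partial-likelihood machinery is delegated to the survival package
# (Efron tie handling, cluster-robust variance); this module owns the
# landmark construction and the risk-scale predictions.

#' Build a landmark-stacked dataset
#'
#' For each landmark time `s`, subjects still at risk (`event_time > s`)
#' contribute one row with a marker summary computed from measurements at
#' times `<= s` and residual time `event_time - s`.  Subjects with no
#' measurement by `s` are dropped at that landmark; the counts are recorded
#' in the `"n_dropped"` attribute.
#'
#' @param data a single-feature [longitudinal_dataset()].
#' @param landmarks landmark times in years.
#' @param summary `"last"` (last observed value by `s`, default) or
#'   `"blup"` (mixed-model current value
#'   `beta0 + b0 + (beta1 + b1) s` from an internal LMM fit, the
#'   partly-conditional literature's smoothed alternative).
#' @param lmm_fit optional pre-computed [fit_lmm()] for `summary = "blup"`.
#' @return data.frame of class `landmark_data` with columns `subject_id`,
#'   `landmark_s`, `marker_value`, `residual_time`, `event`.
#' @export
build_landmark_data <- function(data, landmarks, summary = c("last", "blup"),
                                lmm_fit = NULL) {
  summary <- match.arg(summary)
  if (summary == "blup" && is.null(lmm_fit)) lmm_fit <- fit_lmm(data)
  s_tab <- data$subjects
  m <- data$measurements
  rows <- list(); dropped <- integer(length(landmarks))
  for (k in seq_along(landmarks)) {
    s <- landmarks[k]
    at_risk <- s_tab[s_tab$event_time > s, , drop = FALSE]
    mk <- m[m$time <= s + 1e-12 & m$subject_id %in% at_risk$subject_id, ,
            drop = FALSE]
    marker <- if (summary == "last") {
      .last_value_by_subject(mk)[at_risk$subject_id]
    } else {
      vapply(at_risk$subject_id, function(id) {
        mi <- mk[mk$subject_id == id, , drop = FALSE]
        if (!nrow(mi)) return(NA_real_)
        b <- predict_blup(lmm_fit, mi$time, mi$value)
        unname((lmm_fit$beta[1] + b[1]) + (lmm_fit$beta[2] + b[2]) * s)
      }, 0)
    }
    have <- !is.na(marker)
    dropped[k] <- sum(!have)
    rows[[k]] <- data.frame(
      subject_id = at_risk$subject_id[have], landmark_s = s,
      marker_value = unname(marker[have]),
      residual_time = at_risk$event_time[have] - s,
      event = at_risk$status[have])
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    out <- data.frame(subject_id = character(), landmark_s = numeric(),
                      marker_value = numeric(), residual_time = numeric(),
                      event = integer())
  rownames(out) <- NULL
  class(out) <- c("landmark_data", "data.frame")
  attr(out, "n_dropped") <- stats::setNames(dropped, landmarks)
  out
}

# Run a coxph call capturing its monotone-likelihood (separation) warning.
.coxph_guarded <- function(expr) {
  infinite <- FALSE
  fit <- withCallingHandlers(expr, warning = function(w) {
    if (grepl("infinite|did not converge|out of iterations",
              conditionMessage(w))) {
      infinite <<- TRUE
      invokeRestart("muffleWarning")
    }
  })
  list(fit = fit, infinite = infinite)
}

# Shared post-processing of a coxph fit into the package's cox_fit record.
.cox_fit_record <- function(cph, kind, infinite = FALSE, extra = list()) {
  beta <- unname(stats::coef(cph)[1])
  se <- sqrt(diag(cph$var))[1]          # robust when cluster() was used
  separated <- infinite || (is.finite(beta) && abs(beta) > 15)
  if (separated) {
    warning("monotone partial likelihood (separation); ",
            "coefficient capped at |beta| = 15")
    beta <- sign(beta) * min(abs(beta), 15)
  }
  z <- beta / se
  bh <- survival::basehaz(cph, centered = FALSE)
  structure(c(list(beta_hat = beta, se = se, z = z,
                   p = 2 * stats::pnorm(-abs(z)),
                   loglik = cph$loglik[2], kind = kind,
                   separated = separated, basehaz = bh, converged = TRUE),
              extra),
            class = "cox_fit")
}

#' Partly conditional Cox regression
#'
#' Cox partial-likelihood fit (Efron ties) on landmark-stacked residual
#' times, with subject-clustered robust (sandwich) standard errors because
#' subjects repeat across landmarks.
#'
#' @param landmark_data result of [build_landmark_data()].
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `beta_hat` (log hazard ratio per
#'   abundance unit), robust `se`, `z`, `p`, partial `loglik`, Breslow
#'   `basehaz` on the residual-time scale.
#' @export
fit_pccox <- function(landmark_data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(landmark_data$event) < 1) stop("no events in the stacked data")
  if (stats::sd(landmark_data$marker_value) < 1e-12)
    stop("marker is constant: association not identifiable")
  g <- .coxph_guarded(survival::coxph(
    survival::Surv(residual_time, event) ~ marker_value,
    data = landmark_data, ties = ties,
    cluster = subject_id, x = FALSE, y = TRUE))
  .cox_fit_record(g$fit, "pccox", g$infinite,
                  list(landmarks = sort(unique(landmark_data$landmark_s))))
}

#' Conventional last-value Cox model
#'
#' Standard Cox proportional-hazards fit with each subject's last observed
#' abundance as the only covariate.
#'
#' @param data a single-feature [longitudinal_dataset()].
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit` (see [fit_pccox()]); `kind = "cox"`.
#' @export
fit_cox_last_value <- function(data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  last <- .last_value_by_subject(data$measurements)[data$subjects$subject_id]
  if (any(is.na(last))) stop("every subject needs >= 1 measurement")
  df <- data.frame(marker_value = unname(last),
                   time = data$subjects$event_time,
                   event = data$subjects$status)
  if (sum(df$event) < 1) stop("no events")
  if (stats::sd(df$marker_value) < 1e-12)
    stop("marker is constant: association not identifiable")
  g <- .coxph_guarded(
    survival::coxph(survival::Surv(time, event) ~ marker_value,
                    data = df, ties = ties))
  .cox_fit_record(g$fit, "cox", g$infinite)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(if (x$kind == "pccox") "Partly conditional Cox model"
      else "Last-value Cox model", "\n")
  cat("  log HR ", format(x$beta_hat, digits = 4), " (se ",
      format(x$se, digits = 3), "), z ", format(x$z, digits = 3),
      ", p ", format(x$p, digits = 3), "\n", sep = "")
  if (x$separated) cat("  [monotone likelihood warning]\n")
  invisible(x)
}

# Named vector of each subject's last observed value in a measurement table
# (NA-free; subjects absent from the table are absent from the vector).
.last_value_by_subject <- function(m) {
  if (!nrow(m)) return(stats::setNames(numeric(), character()))
  o <- order(m$subject_id, m$time)
  last <- !duplicated(m$subject_id[o], fromLast = TRUE)
  stats::setNames(m$value[o][last], m$subject_id[o][last])
}

# Step-function cumulative baseline hazard lookup.
.basehaz_at <- function(bh, t) {
  idx <- findInterval(t, bh$time)
  ifelse(idx == 0, 0, bh$hazard[pmax(idx, 1)])
}

#' Risk-scale prediction from a Cox baseline fit
#'
#' Probability of an event by horizon `t` for a subject at risk at `s`,
#' using the marker value last observed by `s` and the Breslow baseline:
#' `1 - exp(-(H0(u2) - H0(u1)) * exp(beta * x))`, on the residual-time scale
#' for the partly conditional model and the study-time scale for the
#' last-value model.  Subjects with no measurement by `s` get `NA`.
#'
#' @param fit a `cox_fit`.
#' @param newdata a [longitudinal_dataset()].
#' @param s years of history used.
#' @param t horizon years, `t >= s`.
#' @return numeric risk vector aligned with `newdata$subjects`.
#' @export
predict_cox_risk <- function(fit, newdata, s, t) {
  if (t < s) stop("require t >= s")
  m <- newdata$measurements[newdata$measurements$time <= s + 1e-12, ,
                            drop = FALSE]
  subj <- newdata$subjects
  marker <- unname(.last_value_by_subject(m)[subj$subject_id])
  lp <- pmin(fit$beta_hat * marker, 700)
  dH <- if (fit$kind == "pccox") {
    .basehaz_at(fit$basehaz, t - s)
  } else {
    .basehaz_at(fit$basehaz, t) - .basehaz_at(fit$basehaz, s)
  }
  pmin(pmax(1 - exp(-dH * exp(lp)), 0), 1)
}
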