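# Proteome-wide screening strategy: per-feature model fitting with automated
# selection, multiplicity control, AUROC-based prioritisation at successive
# evaluation ages, cross-method consensus, and leave-one-out
# cross-validation as the overfitting check.

#' Screening configuration
#'
#' @param eval_ages ages (years) at which predictive ability is evaluated
#'   (default `c(5, 6, 7, 8)`; must be ascending).
#' @param horizon_age age at which disease status is predicted (default 13).
#' @param min_peptides minimum unique-peptide count (default 6, inclusive).
#' @param max_missing maximum missing-value count over all samples
#'   (default 10, inclusive).
#' @param auroc_threshold minimum AUROC (default 0.75).
#' @param auroc_last_k the AUROC threshold must hold in at least the last
#'   `auroc_last_k` evaluation ages (default 2).
#' @param min_per_class minimum subjects with measurements per class
#'   (default 5; the flag requires strictly more informative data than
#'   "fewer than 5 in either class").
#' @param p_thresholds named per-method significance thresholds
#'   (default `jm = 0.05`, `pccox = 0.01`).
#' @param consensus_k minimum number of selecting methods for the consensus
#'   set (default 2).
#' @param use_adjusted use BH-adjusted rather than nominal p-values for
#'   selection (default FALSE).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(eval_ages = c(5, 6, 7, 8), horizon_age = 13,
                          min_peptides = 6, max_missing = 10,
                          auroc_threshold = 0.75, auroc_last_k = 2,
                          min_per_class = 5,
                          p_thresholds = c(jm = 0.05, pccox = 0.01),
                          consensus_k = 2, use_adjusted = FALSE) {
  stopifnot(!is.unsorted(eval_ages), horizon_age > max(eval_ages),
            auroc_threshold >= 0, auroc_threshold <= 1,
            auroc_last_k >= 1, auroc_last_k <= length(eval_ages),
            all(p_thresholds > 0 & p_thresholds <= 1))
  structure(list(eval_ages = eval_ages, horizon_age = horizon_age,
                 min_peptides = min_peptides, max_missing = max_missing,
                 auroc_threshold = auroc_threshold,
                 auroc_last_k = auroc_last_k, min_per_class = min_per_class,
                 p_thresholds = p_thresholds, consensus_k = consensus_k,
                 use_adjusted = use_adjusted),
            class = "screen_config")
}

#' Peptide/missingness prefilter
#'
#' Keeps a feature iff `n_peptides >= min_peptides` and
#' `n_missing <= max_missing` (both boundaries inclusive).  Features with
#' missing metadata are excluded with a warning.
#'
#' @param features feature metadata data.frame (`feature_id`, `n_peptides`,
#'   `n_missing`).
#' @param config a [screen_config()].
#' @return character vector of kept feature ids.
#' @export
prefilter <- function(features, config = screen_config()) {
  bad <- is.na(features$n_peptides) | is.na(features$n_missing)
  if (any(bad))
    warning(sum(bad), " feature(s) lack metadata and are excluded")
  keep <- !bad & features$n_peptides >= config$min_peptides &
    features$n_missing <= config$max_missing
  features$feature_id[keep]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj[(i)] = min_{j >= i} ( m * p_(j) / j )` capped at 1, returned in
#' the input order; controls the false discovery rate under independence.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   preserved).
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))[order(o)]
    out[ok] <- adj
  }
  out
}

# Count of subjects with >= 1 measurement for the feature, per class.
.class_counts <- function(fdata) {
  have <- unique(fdata$measurements$subject_id)
  grp <- fdata$subjects$group[fdata$subjects$subject_id %in% have]
  c(case = sum(grp == "case"), control = sum(grp == "control"))
}

#' Screen one feature with one method
#'
#' Fits the chosen method on the feature's full history (resubstitution, as
#' in the screening strategy; LOO-CV is the honesty check), computes the
#' association evidence (Wald p for the joint model, robust partial-
#' likelihood Wald p for the partly conditional Cox model, BIC two-class
#' selection with the class-size constraint for the latent-class model) and
#' the AUROC for predicting status at `horizon_age` from measurements at
#' ages `<= a` for every evaluation age `a`.
#'
#' @param data the full cohort [longitudinal_dataset()].
#' @param feature_id feature to screen (should have passed [prefilter()]).
#' @param method one of `"jm"`, `"pccox"`, `"lcmm"`.
#' @param config a [screen_config()].
#' @param seed seed for stochastic initialisation search (lcmm).
#' @return one-row data.frame (`screen_row`): `feature_id`, `method`, `p`,
#'   `auroc_<age>` columns, `passed_prefilter`, `passed_auroc`,
#'   `passed_class_size`, `converged`, `evidence` (method-specific selection
#'   evidence before the AUROC/class-size stages), `reason`.
#' @export
screen_feature <- function(data, feature_id, method, config = screen_config(),
                           seed = 1L) {
  fdata <- single_feature(data, feature_id)
  cc <- .class_counts(fdata)
  row <- data.frame(feature_id = feature_id, method = method, p = NA_real_,
                    converged = FALSE, evidence = FALSE,
                    passed_prefilter = TRUE,
                    passed_class_size = all(cc >= config$min_per_class),
                    passed_auroc = FALSE, ng = NA_integer_, reason = "")
  for (a in config$eval_ages) row[[paste0("auroc_", a)]] <- NA_real_

  fit <- try(suppressWarnings(switch(method,
    jm = fit_joint_model(fdata),
    pccox = fit_pccox(build_landmark_data(fdata, config$eval_ages)),
    lcmm = select_ng(fdata, candidates = 1:2, seed = seed),
    stop("unknown method: ", method))), silent = TRUE)
  if (inherits(fit, "try-error")) {
    row$reason <- "fit_error"
    return(row)
  }
  row$converged <- .method_converged(fit)
  if (!row$converged) {
    row$reason <- "non_convergence"
    return(row)
  }

  if (method == "jm") {
    row$p <- wald_test(fit)$p
  } else if (method == "pccox") {
    row$p <- fit$p
  } else {
    row$ng <- fit$ng
    # evidence = two classes by BIC, both with > min_per_class subjects
    row$evidence <- fit$ng == 2 && all(fit$class_sizes > config$min_per_class)
  }

  aucs <- rep(NA_real_, length(config$eval_ages))
  for (k in seq_along(config$eval_ages)) {
    a <- config$eval_ages[k]
    risk <- try(suppressWarnings(
      .predict_method(method, fit, fdata, a, config$horizon_age)),
      silent = TRUE)
    if (!inherits(risk, "try-error")) {
      aucs[k] <- auroc(risk, fdata$subjects$group == "case")$auroc
      row[[paste0("auroc_", a)]] <- aucs[k]
    }
  }
  last <- utils::tail(seq_along(config$eval_ages), config$auroc_last_k)
  row$passed_auroc <- all(!is.na(aucs[last]) &
                            aucs[last] >= config$auroc_threshold)
  row
}

.screen_selected <- function(rows, config) {
  pcol <- if (config$use_adjusted) rows$p_adj else rows$p
  thr <- config$p_thresholds[rows$method]
  sig <- ifelse(rows$method == "lcmm", rows$evidence,
                !is.na(pcol) & !is.na(thr) & pcol < thr)
  sig & rows$passed_prefilter & rows$passed_class_size & rows$passed_auroc &
    rows$converged
}

#' Screen a cohort across features and methods
#'
#' Applies [prefilter()], screens every kept feature with every method, and
#' adds per-method BH-adjusted p-values and the final selection flag
#' (`selected` requires all pass flags plus the method's significance rule
#' on the nominal p by default, or the adjusted p with
#' `config$use_adjusted`).
#'
#' @param data the cohort [longitudinal_dataset()].
#' @param methods subset of `c("jm", "pccox", "lcmm")`.
#' @param config a [screen_config()].
#' @param seed integer seed.
#' @param progress print a dot per 50 features (default FALSE).
#' @return data.frame with one row per feature x method; features dropped by
#'   the prefilter appear once per method with `passed_prefilter = FALSE`.
#' @export
screen_cohort <- function(data, methods = c("jm", "pccox"),
                          config = screen_config(), seed = 1L,
                          progress = FALSE) {
  kept <- prefilter(data$features, config)
  rows <- list()
  for (method in methods) {
    for (i in seq_along(kept)) {
      rows[[length(rows) + 1L]] <-
        screen_feature(data, kept[i], method, config, seed = seed)
      if (progress && i %% 50 == 0) cat(".")
    }
    dropped <- setdiff(data$features$feature_id, kept)
    for (fid in dropped) {
      r <- data.frame(feature_id = fid, method = method, p = NA_real_,
                      converged = NA, evidence = FALSE,
                      passed_prefilter = FALSE, passed_class_size = NA,
                      passed_auroc = NA, ng = NA_integer_,
                      reason = "prefilter")
      for (a in config$eval_ages) r[[paste0("auroc_", a)]] <- NA_real_
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (method in methods) {
    idx <- out$method == method & out$passed_prefilter
    out$p_adj[idx] <- bh_adjust(out$p[idx])
  }
  out$selected <- .screen_selected(out, config)
  rownames(out) <- NULL
  out
}

#' Cross-method consensus set
#'
#' Features selected by at least `consensus_k` distinct methods.
#'
#' @param rows result of [screen_cohort()] (>= 2 methods).
#' @param config a [screen_config()].
#' @return data.frame `feature_id`, `n_methods`, `methods` (comma-joined),
#'   one row per consensus feature.
#' @export
consensus <- function(rows, config = screen_config()) {
  if (length(unique(rows$method)) < 2)
    stop("consensus requires >= 2 screened methods")
  sel <- rows[rows$selected %in% TRUE, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(feature_id = character(), n_methods = integer(),
                      methods = character()))
  agg <- stats::aggregate(method ~ feature_id, data = sel,
                          FUN = function(m) paste(sort(unique(m)),
                                                  collapse = ","))
  agg$n_methods <- lengths(strsplit(agg$method, ","))
  out <- agg[agg$n_methods >= config$consensus_k,
             c("feature_id", "n_methods", "method")]
  names(out)[3] <- "methods"
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated AUROC for selected features
#'
#' For each feature and each left-out subject, refits the method on the
#' remaining subjects and predicts the left-out subject's risk of the event
#' by `horizon_age` from their history up to each evaluation age; the pooled
#' out-of-fold predictions give one AUROC per evaluation age.  Folds whose
#' refit fails are dropped from the pooling and counted.
#'
#' @param data the cohort [longitudinal_dataset()].
#' @param features feature ids to cross-validate.
#' @param method one of `"jm"`, `"pccox"`, `"lcmm"`.
#' @param config a [screen_config()].
#' @param seed integer seed.
#' @return data.frame with `feature_id`, `eval_age`, `auroc`, `n_folds_ok`,
#'   `n_folds_failed`.
#' @export
loocv_screen <- function(data, features, method, config = screen_config(),
                         seed = 1L) {
  stopifnot(length(features) >= 1)
  subj <- data$subjects
  if (nrow(subj) <= 2)
    warning("degenerate LOO-CV: each training fold has <= 1 subject")
  out <- list()
  for (fid in features) {
    fdata <- single_feature(data, fid)
    preds <- array(NA_real_, c(nrow(subj), length(config$eval_ages)))
    failed <- 0L
    for (i in seq_len(nrow(subj))) {
      keep <- subj$subject_id[-i]
      train <- longitudinal_dataset(
        fdata$measurements[fdata$measurements$subject_id %in% keep, ,
                           drop = FALSE],
        subj[-i, , drop = FALSE], fdata$features, validate = FALSE)
      hold <- longitudinal_dataset(
        fdata$measurements[fdata$measurements$subject_id ==
                             subj$subject_id[i], , drop = FALSE],
        subj[i, , drop = FALSE], fdata$features, validate = FALSE)
      fit <- try(suppressWarnings(
        .fit_method(method, train, config = list(landmarks = config$eval_ages),
                    seed = seed)), silent = TRUE)
      if (inherits(fit, "try-error") || !.method_converged(fit)) {
        failed <- failed + 1L
        next
      }
      for (k in seq_along(config$eval_ages)) {
        r <- try(suppressWarnings(
          .predict_method(method, fit, hold, config$eval_ages[k],
                          config$horizon_age)), silent = TRUE)
        if (!inherits(r, "try-error")) preds[i, k] <- r[1]
      }
    }
    for (k in seq_along(config$eval_ages)) {
      a <- auroc(preds[, k], subj$group == "case")
      out[[length(out) + 1L]] <- data.frame(
        feature_id = fid, eval_age = config$eval_ages[k], auroc = a$auroc,
        n_folds_ok = nrow(subj) - failed, n_folds_failed = failed)
    }
  }
  do.call(rbind, out)
}
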