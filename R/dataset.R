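# Long-format container for longitudinal biomarker studies: a measurements
# table, a subjects table (event time, status, group), and feature metadata.

#' Construct a longitudinal dataset
#'
#' Bundles the three long-format tables used throughout the package and
#' validates their referential integrity.
#'
#' @param measurements data.frame with columns `subject_id`, `time` (years),
#'   `feature_id`, `value` (abundance, typically log-scale).
#' @param subjects data.frame with columns `subject_id`, `event_time` (years),
#'   `status` (1 = event observed, 0 = censored), `group`
#'   (`"case"`/`"control"`).
#' @param features data.frame with columns `feature_id`, `n_peptides`,
#'   `n_missing`; may be `NULL`, in which case a stub with `NA` metadata is
#'   built from the measurement table.
#' @param validate check invariants (referential integrity, no post-event
#'   measurements for cases, status/group consistency when both present).
#' @return object of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(measurements, subjects, features = NULL,
                                 validate = TRUE) {
  measurements <- as.data.frame(measurements)
  subjects <- as.data.frame(subjects)
  need_m <- c("subject_id", "time", "feature_id", "value")
  need_s <- c("subject_id", "event_time", "status", "group")
  if (!all(need_m %in% names(measurements)))
    stop("measurements must have columns: ", paste(need_m, collapse = ", "))
  if (!all(need_s %in% names(subjects)))
    stop("subjects must have columns: ", paste(need_s, collapse = ", "))
  if (is.null(features)) {
    features <- data.frame(feature_id = unique(measurements$feature_id),
                           n_peptides = NA_integer_, n_missing = NA_integer_)
  }
  features <- as.data.frame(features)
  x <- structure(list(measurements = measurements, subjects = subjects,
                      features = features),
                 class = "longitudinal_dataset")
  if (validate) validate_dataset(x)
  x
}

validate_dataset <- function(x) {
  m <- x$measurements; s <- x$subjects
  if (anyDuplicated(s$subject_id))
    stop("duplicate subject_id in subjects table")
  if (anyDuplicated(m[c("subject_id", "time", "feature_id")]))
    stop("duplicate (subject_id, time, feature_id) measurement rows")
  bad <- setdiff(m$subject_id, s$subject_id)
  if (length(bad))
    stop("measurements reference unknown subject_id: ",
         paste(utils::head(bad, 3), collapse = ", "))
  bad <- setdiff(m$feature_id, x$features$feature_id)
  if (length(bad))
    stop("measurements reference unknown feature_id: ",
         paste(utils::head(bad, 3), collapse = ", "))
  if (!all(s$status %in% c(0, 1))) stop("status must be 0/1")
  ev <- s$event_time[match(m$subject_id, s$subject_id)]
  st <- s$status[match(m$subject_id, s$subject_id)]
  late <- st == 1 & m$time > ev + 1e-9
  if (any(late))
    stop("post-event measurement(s) found for subject(s): ",
         paste(utils::head(unique(m$subject_id[late]), 3), collapse = ", "))
  invisible(x)
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat("longitudinal_dataset:",
      nrow(x$subjects), "subjects,",
      nrow(x$features), "features,",
      nrow(x$measurements), "measurements\n")
  tab <- table(x$subjects$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  events:", sum(x$subjects$status), "observed,",
      sum(x$subjects$status == 0), "censored\n")
  invisible(x)
}

# Restrict a dataset to one feature (drops the feature_id dimension for the
# single-feature model fitters, which operate on subject/time/value only).
single_feature <- function(data, feature_id) {
  m <- data$measurements
  m <- m[m$feature_id == feature_id, , drop = FALSE]
  longitudinal_dataset(m, data$subjects,
                       data$features[data$features$feature_id == feature_id, ,
                                     drop = FALSE],
                       validate = FALSE)
}

feature_ids <- function(data) unique(data$features$feature_id)
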