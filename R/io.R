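# CSV serialisation of longitudinal datasets.  One directory per dataset:
# measurements.csv, subjects.csv, features.csv (comma-separated, header row,
# UTF-8, '.' decimal separator).

#' Write a longitudinal dataset to a directory of CSV files
#'
#' @param data a [longitudinal_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  s <- data$subjects[c("subject_id", "event_time", "status", "group")]
  utils::write.csv(s, file.path(dir, "subjects.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(data$features, file.path(dir, "features.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

.read_checked <- function(path, cols) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read a longitudinal dataset from a directory of CSV files
#'
#' Counterpart of [write_dataset()]; validates the schema, coerces times and
#' values to numeric (reporting the file, line and column of the first
#' failure), rejects duplicate `(subject, time, feature)` rows and post-event
#' case measurements.
#'
#' @param path dataset directory containing `measurements.csv`,
#'   `subjects.csv` and (optionally) `features.csv`.
#' @return a validated [longitudinal_dataset()].
#' @export
read_long_table <- function(path) {
  m <- .read_checked(file.path(path, "measurements.csv"),
                     c("subject_id", "time", "feature_id", "value"))
  s <- .read_checked(file.path(path, "subjects.csv"),
                     c("subject_id", "event_time", "status", "group"))
  fpath <- file.path(path, "features.csv")
  f <- if (file.exists(fpath))
    .read_checked(fpath, c("feature_id", "n_peptides", "n_missing")) else NULL
  for (col in c("time", "value")) {
    v <- suppressWarnings(as.numeric(m[[col]]))
    bad <- which(is.na(v) & !is.na(m[[col]]))
    if (length(bad))
      stop("measurements.csv line ", bad[1] + 1L, ", column '", col,
           "': not a number: ", m[[col]][bad[1]])
    m[[col]] <- v
  }
  s$event_time <- as.numeric(s$event_time)
  s$status <- as.integer(s$status)
  longitudinal_dataset(m, s, f, validate = TRUE)
}
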