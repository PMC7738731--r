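# Long-format weight records: one row per (puppy, day) measurement.
# Canonical columns: puppy_id, litter_id, breed, sex, day, weight_g.

record_columns <- c("puppy_id", "litter_id", "breed", "sex", "day", "weight_g")

#' Validate a table of weight records
#'
#' Checks the canonical long-format schema for daily weight series:
#' columns `puppy_id, litter_id, breed, sex, day, weight_g`, positive
#' weights, non-negative integer days, sex in
#' `{male, female, unknown}`, and uniqueness of `(puppy_id, day)`.
#'
#' @param records A data.frame of weight measurements.
#' @return The validated data.frame (sorted by puppy then day),
#'   invisibly usable downstream.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols)) {
    stop("missing record columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  if (!is.numeric(records$weight_g) || any(!is.finite(records$weight_g)) ||
      any(records$weight_g <= 0)) {
    stop("`weight_g` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(records$day) || any(!is.finite(records$day)) ||
      any(records$day < 0) || any(records$day != round(records$day))) {
    stop("`day` must be a non-negative integer", call. = FALSE)
  }
  bad_sex <- setdiff(unique(as.character(records$sex)),
                     c("male", "female", "unknown"))
  if (length(bad_sex)) {
    stop("`sex` must be one of male/female/unknown; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  key <- paste(records$puppy_id, records$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate measurement for puppy '%s' on day %d",
                 dup$puppy_id, as.integer(dup$day)), call. = FALSE)
  }
  records <- records[order(records$puppy_id, records$day), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Write a weight-record dataset to CSV
#'
#' Fixed header `puppy_id,litter_id,breed,sex,day,weight_g`; plain
#' unquoted CSV so the file round-trips exactly through
#' [load_dataset()].
#'
#' @param records A validated record data.frame (see
#'   [validate_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dataset <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records[, record_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weight-record dataset from CSV
#'
#' Parses and validates a long-format daily-weight CSV. Malformed rows
#' (wrong field count, non-numeric day or weight) are reported with
#' their line number; non-positive weights and duplicate
#' `(puppy_id, day)` pairs are rejected.
#'
#' @param path CSV path with header
#'   `puppy_id,litter_id,breed,sex,day,weight_g`.
#' @return A validated data.frame of weight records.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("dataset has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(header, record_columns)) {
    stop("unexpected header; need: ", paste(record_columns, collapse = ","),
         call. = FALSE)
  }
  fields <- strsplit(lines[-1L], ",", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != length(record_columns))
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields, found %d",
                 bad[1L] + 1L, length(record_columns), n_fields[bad[1L]]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  day <- suppressWarnings(as.numeric(m[, 5L]))
  weight <- suppressWarnings(as.numeric(m[, 6L]))
  if (anyNA(day)) {
    stop(sprintf("line %d: non-numeric day '%s'",
                 which(is.na(day))[1L] + 1L, m[which(is.na(day))[1L], 5L]),
         call. = FALSE)
  }
  if (anyNA(weight)) {
    stop(sprintf("line %d: non-numeric weight '%s'",
                 which(is.na(weight))[1L] + 1L, m[which(is.na(weight))[1L], 6L]),
         call. = FALSE)
  }
  if (any(weight <= 0)) {
    stop(sprintf("line %d: non-positive weight %g",
                 which(weight <= 0)[1L] + 1L, weight[which(weight <= 0)[1L]]),
         call. = FALSE)
  }
  if (any(day != round(day))) {
    stop(sprintf("line %d: fractional day %g",
                 which(day != round(day))[1L] + 1L,
                 day[which(day != round(day))[1L]]), call. = FALSE)
  }
  records <- data.frame(
    puppy_id = m[, 1L], litter_id = m[, 2L], breed = m[, 3L], sex = m[, 4L],
    day = as.integer(round(day)), weight_g = weight,
    stringsAsFactors = FALSE)
  validate_records(records)
}

# Restrict records to an age window [lo, hi] in days.
window_records <- function(records, day_window) {
  stopifnot(length(day_window) == 2L, day_window[1L] <= day_window[2L])
  records[records$day >= day_window[1L] & records$day <= day_window[2L], ,
          drop = FALSE]
}
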