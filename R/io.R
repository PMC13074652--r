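#' Validate a plant-record table
#'
#' Checks the column set, types and levels of a record table: exactly the
#' documented columns, numeric traits/targets, treatments among CT/RB/FR,
#' seasons among spring/winter, non-negative lengths and targets, strictly
#' positive height and diameters, and no missing values.
#'
#' @param records data.frame to validate.
#' @return the validated records, invisibly.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame", call. = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(records), RECORD_COLUMNS)
  if (length(unknown)) {
    stop(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  num_cols <- c("year", "dat", "pruning", TRAIT_COLUMNS, TARGET_COLUMNS)
  for (cl in num_cols) {
    if (!is.numeric(records[[cl]])) {
      stop(sprintf("column '%s' must be numeric", cl), call. = FALSE)
    }
  }
  if (anyNA(records[RECORD_COLUMNS])) stop("records contain missing values", call. = FALSE)
  bad_tr <- setdiff(unique(records$treatment), TREATMENT_LEVELS)
  if (length(bad_tr)) {
    stop(sprintf(
      "unknown treatment level(s) %s; allowed levels are {%s}",
      paste(bad_tr, collapse = ", "), paste(TREATMENT_LEVELS, collapse = ", ")
    ), call. = FALSE)
  }
  bad_se <- setdiff(unique(records$season), SEASON_LEVELS)
  if (length(bad_se)) {
    stop(sprintf(
      "unknown season level(s) %s; allowed levels are {%s}",
      paste(bad_se, collapse = ", "), paste(SEASON_LEVELS, collapse = ", ")
    ), call. = FALSE)
  }
  if (any(records$dat < 0)) stop("dat must be >= 0", call. = FALSE)
  if (!all(records$pruning %in% c(0, 1))) stop("pruning must be 0/1", call. = FALSE)
  if (!is.logical(records$is_synthetic)) stop("is_synthetic must be logical", call. = FALSE)
  strict_pos <- c("plant_height", "basal_stem_diam", "main_stem_diam", "left_stem_diam", "right_stem_diam")
  for (cl in strict_pos) {
    if (any(records[[cl]] <= 0)) stop(sprintf("column '%s' must be strictly positive", cl), call. = FALSE)
  }
  nonneg <- c("main_stem_len", "left_stem_len", "right_stem_len", TARGET_COLUMNS)
  for (cl in nonneg) {
    if (any(records[[cl]] < 0)) stop(sprintf("column '%s' must be non-negative", cl), call. = FALSE)
  }
  invisible(records)
}

#' Write / read plant-record tables as CSV
#'
#' Plain UTF-8 CSV with the documented header; the round trip is lossless.
#' `read_records()` rejects tables with missing or unknown columns and
#' invalid categorical levels.
#'
#' @param records data.frame of plant records.
#' @param path file path.
#' @return `read_records()` returns the validated record table;
#'   `write_records()` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  out <- records[, RECORD_COLUMNS]
  # print doubles at 17 significant digits so the CSV round trip is exact
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                             colClasses = c(source_group = "character"))
  if ("is_synthetic" %in% names(records)) {
    records$is_synthetic <- as.logical(records$is_synthetic)
  }
  if ("source_group" %in% names(records)) {
    records$source_group[is.na(records$source_group)] <- ""
  }
  validate_records(records)
  records
}
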