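#' Read a cohort CSV
#'
#' The cohort file is a flat UTF-8 CSV with a header row and the fixed column
#' set `respondent_id, age, gender, latency_years, disease_group,
#' diagnostic_system, exact_diagnosis, q01..q53`. Unknown latency and unknown
#' diagnosis fields are stored as the literal token `"unknown"`; on reading,
#' unknown latency becomes `NA` while unknown diagnoses keep the token.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default) any invalid row aborts with an error
#'   naming the row and column; if `FALSE`, invalid rows are dropped with a
#'   warning and the remaining rows are returned.
#' @return A validated cohort data frame, rows in file order, with a
#'   `provenance` attribute recording the source path.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_data(paste0("cohort file not found: ", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(cohort_columns(), names(df))
  extra <- setdiff(names(df), cohort_columns())
  if (length(missing) || length(extra))
    stop_data(paste0("cohort CSV schema mismatch",
                     if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
                     if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))))
  df <- df[cohort_columns()]
  if (nrow(df) == 0L) stop_data("cohort CSV has no data rows")
  if (anyDuplicated(df$respondent_id))
    stop_data(paste0("duplicate respondent_id: ",
                     df$respondent_id[duplicated(df$respondent_id)][1]))

  bad_rows <- character(0)
  note_bad <- function(row, col, val) {
    msg <- sprintf("row %d, column %s (value '%s')", row, col, val)
    if (strict) stop_data(paste0("invalid cohort value: ", msg))
    bad_rows <<- c(bad_rows, msg)
  }

  age <- suppressWarnings(as.integer(df$age))
  for (i in which(is.na(age) | age < 0)) note_bad(i, "age", df$age[i])

  gender <- tolower(trimws(df$gender))
  gender[gender %in% c("other/unknown", "unknown", "")] <- "other"
  for (i in which(!gender %in% .GENDERS)) note_bad(i, "gender", df$gender[i])

  lat_raw <- trimws(df$latency_years)
  lat <- suppressWarnings(as.numeric(lat_raw))
  lat[lat_raw %in% c("unknown", "")] <- NA_real_
  for (i in which(!is.na(lat_raw) & !(lat_raw %in% c("unknown", "")) &
                  (is.na(lat) | lat < 0)))
    note_bad(i, "latency_years", df$latency_years[i])

  dsys <- trimws(df$diagnostic_system)
  for (i in which(!dsys %in% .DIAG_SYSTEMS)) note_bad(i, "diagnostic_system", df$diagnostic_system[i])

  ans <- suppressWarnings(matrix(as.integer(as.matrix(df[.ANSWER_COLS])),
                                 nrow = nrow(df)))
  bad_ans <- which(is.na(ans) | ans < 1L | ans > 5L)
  for (b in bad_ans) {
    ij <- arrayInd(b, dim(ans))
    note_bad(ij[1], .ANSWER_COLS[ij[2]], df[[.ANSWER_COLS[ij[2]]]][ij[1]])
  }

  out <- data.frame(
    respondent_id = df$respondent_id,
    age = age,
    gender = gender,
    latency_years = lat,
    disease_group = ifelse(trimws(df$disease_group) == "", "unknown",
                           trimws(df$disease_group)),
    diagnostic_system = dsys,
    exact_diagnosis = ifelse(trimws(df$exact_diagnosis) == "", "unknown",
                             trimws(df$exact_diagnosis)),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(ans))
  names(out) <- cohort_columns()

  if (length(bad_rows)) {
    warning(sprintf("dropped %d invalid row(s): %s",
                    length(unique(sub(",.*", "", bad_rows))),
                    paste(bad_rows, collapse = "; ")), call. = FALSE)
    drop <- unique(as.integer(sub("^row (\\d+).*", "\\1", bad_rows)))
    out <- out[-drop, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out) == 0L) stop_data("no valid rows remain after filtering")
  }
  validate_cohort(out)
  attr(out, "provenance") <- paste0("read from ", path)
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the documented 60-column schema,
#' loss-free for all fields. Unknown latency (`NA`) and empty diagnosis
#' strings are serialized as the explicit token `"unknown"`, never as empty
#' cells.
#'
#' @param cohort A valid cohort data frame.
#' @param path Output file path.
#' @return The output path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[cohort_columns()]
  out$latency_years <- ifelse(is.na(out$latency_years), "unknown",
                              as.character(out$latency_years))
  for (cn in c("disease_group", "exact_diagnosis"))
    out[[cn]] <- ifelse(is.na(out[[cn]]) | trimws(out[[cn]]) == "", "unknown", out[[cn]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_data(paste0("cannot write cohort to ", path, ": ",
                                    conditionMessage(ok)))
  invisible(path)
}
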