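#' The Q53 instrument
#'
#' The matching core operates on a 53-item questionnaire whose answers are
#' coded 1 = No, 2 = Slightly no, 3 = Slightly yes, 4 = Yes, 5 = Do not know.
#' The items fall into 7 thematic categories. Item texts are never used in any
#' computation; matching depends only on the numeric codes, so the bundled
#' instrument definition carries synthetic placeholder labels.
#'
#' @return A data frame with one row per item and columns `id` ("q01".."q53"),
#'   `category` (integer 1..7) and `text`.
#' @examples
#' q <- instrument_questions()
#' nrow(q)           # 53
#' table(q$category) # 7 categories
#' @export
instrument_questions <- function() {
  if (is.null(.q53_cache$questions)) {
    path <- system.file("extdata", "instrument.json", package = "q53match")
    q <- jsonlite::fromJSON(path)
    stopifnot(nrow(q) == 53L, !anyDuplicated(q$id),
              all(q$category %in% 1:7), length(unique(q$category)) == 7L)
    .q53_cache$questions <- q
  }
  .q53_cache$questions
}

.q53_cache <- new.env(parent = emptyenv())

.ANSWER_COLS <- sprintf("q%02d", 1:53)
.META_COLS <- c("respondent_id", "age", "gender", "latency_years",
                "disease_group", "diagnostic_system", "exact_diagnosis")
.DIAG_SYSTEMS <- c("RD", "CD", "psychosomatic", "healthy", "unknown")
.GENDERS <- c("female", "male", "other")

#' Cohort CSV column order
#'
#' @return Character vector naming the 60 columns of the cohort CSV schema:
#'   seven metadata columns followed by `q01`..`q53`.
#' @export
cohort_columns <- function() c(.META_COLS, .ANSWER_COLS)

#' Validate a cohort table
#'
#' Checks the invariants of the cohort data model: all 60 schema columns
#' present, at least one respondent, unique respondent ids, non-negative
#' integer ages, genders and diagnostic systems from their closed sets,
#' non-negative (or unknown, i.e. `NA`) latencies, answers all in 1..5, and
#' healthy respondents carrying the exact diagnosis `"healthy"`.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @return The cohort, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop_data("cohort must be a data frame")
  missing <- setdiff(cohort_columns(), names(cohort))
  extra <- setdiff(names(cohort), cohort_columns())
  if (length(missing)) stop_data(paste0("missing cohort column(s): ",
                                        paste(missing, collapse = ", ")))
  if (length(extra)) stop_data(paste0("unexpected cohort column(s): ",
                                      paste(extra, collapse = ", ")))
  if (nrow(cohort) == 0L) stop_data("cohort is empty")
  if (anyDuplicated(cohort$respondent_id))
    stop_data(paste0("duplicate respondent_id: ",
                     cohort$respondent_id[duplicated(cohort$respondent_id)][1]))
  if (any(is.na(cohort$age)) || any(cohort$age < 0))
    stop_data("age must be a non-negative integer")
  if (!all(cohort$gender %in% .GENDERS))
    stop_data(paste0("gender must be one of: ", paste(.GENDERS, collapse = ", ")))
  if (!all(cohort$diagnostic_system %in% .DIAG_SYSTEMS))
    stop_data(paste0("diagnostic_system must be one of: ",
                     paste(.DIAG_SYSTEMS, collapse = ", ")))
  lat <- cohort$latency_years
  if (any(!is.na(lat) & lat < 0)) stop_data("latency_years must be >= 0 or unknown")
  healthy <- cohort$diagnostic_system == "healthy"
  if (any(cohort$exact_diagnosis[healthy] != "healthy"))
    stop_data("healthy respondents must have exact_diagnosis 'healthy'")
  ans <- as.matrix(cohort[.ANSWER_COLS])
  bad <- which(!(ans %in% 1:5))
  if (length(bad)) {
    bad1 <- arrayInd(bad[1], dim(ans))
    stop_data(sprintf("answer out of range in row %d, column %s (value %s)",
                      bad1[1], .ANSWER_COLS[bad1[2]], ans[bad[1]]))
  }
  invisible(cohort)
}

#' Extract the answer matrix of a cohort
#'
#' @param cohort A cohort data frame.
#' @return An n x 53 numeric matrix of answer codes, row names the respondent
#'   ids. This is the feature matrix every distance measure consumes.
#' @export
answer_matrix <- function(cohort) {
  m <- as.matrix(cohort[.ANSWER_COLS])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$respondent_id
  m
}

#' Recode "Do not know" answers to a neutral value
#'
#' "Do not know" is coded 5 and by default enters the distance arithmetic
#' literally, which places it beyond "Yes" on the ordinal scale. This optional
#' preprocessing replaces code 5 by a neutral midpoint before matching.
#'
#' @param x A cohort data frame or an answer matrix.
#' @param value Replacement value, default 2.5 (the midpoint of the 1..4
#'   ordinal range).
#' @return Object of the same shape with every answer code 5 replaced.
#' @export
impute_dont_know <- function(x, value = 2.5) {
  if (is.data.frame(x)) {
    for (cn in .ANSWER_COLS) {
      v <- as.numeric(x[[cn]])
      v[v == 5] <- value
      x[[cn]] <- v
    }
    x
  } else {
    x[x == 5] <- value
    x
  }
}
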