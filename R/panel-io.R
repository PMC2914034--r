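#' Validate a long-format person-round panel
#'
#' Checks the structural invariants every downstream stage relies on: the
#' full column schema is present, indicator columns are strictly 0/1,
#' utilization counts are non-negative integers, rounds within each person
#' are consecutive `1..T` with no gaps, every person is observed for the
#' same number of rounds, and covariates that are defined as time-constant
#' (age at baseline, sex, race, education, marital status, family size,
#' chronic-condition count) do not vary within person.
#'
#' The complete-panel rule mirrors the analysis sample restriction of
#' two-year panel surveys: only individuals observed in every round are
#' analyzed.  By default an incomplete person is an error, so the sample
#' can never shrink silently; set `drop_incomplete = TRUE` to drop such
#' persons explicitly.
#'
#' @param panel A data frame with one row per person-round using the
#'   canonical schema (see [read_panel()] for the column list).
#' @param drop_incomplete Drop persons whose round sequence is not the full
#'   `1..T` instead of raising an error.  Default `FALSE`.
#' @return The validated panel as a tibble, sorted by person and round,
#'   with `person_id` coerced to character and integer-valued columns
#'   stored as integers.
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_persons = 20, seed = 1))
#' p <- validate_panel(sim$panel)
#' n_rounds(p)
validate_panel <- function(panel, drop_incomplete = FALSE) {
  if (!is.data.frame(panel)) {
    abort("`panel` must be a data frame.", class = "medchurn_schema_error")
  }
  missing_cols <- setdiff(panel_schema(), names(panel))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Panel is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "medchurn_schema_error"
    )
  }
  panel <- as_tibble(panel)[panel_schema()]
  panel$person_id <- as.character(panel$person_id)
  if (nrow(panel) == 0) {
    return(panel)
  }

  check_numeric <- function(col) {
    if (!is.numeric(panel[[col]])) {
      abort(paste0("Column `", col, "` must be numeric."),
            class = "medchurn_validation_error")
    }
  }
  bad_row_msg <- function(col, bad, what) {
    rows <- which(bad)
    abort(
      paste0("Column `", col, "` ", what, " (first offending row: ",
             rows[1], ", person ", panel$person_id[rows[1]], ", round ",
             panel$round[rows[1]], ")."),
      class = "medchurn_validation_error"
    )
  }

  int_cols <- c("round", "er_visits", "outpatient_visits",
                "inpatient_discharges", "rx_fills", "family_size",
                "chronic_count")
  bin_cols <- c("medicaid", "employed", "healthy", "male", "married",
                "high_school", "white")
  for (col in setdiff(panel_schema(), "person_id")) check_numeric(col)
  for (col in int_cols) {
    x <- panel[[col]]
    bad <- !is.finite(x) | x != round(x)
    if (any(bad)) bad_row_msg(col, bad, "must be integral")
  }
  for (col in c("er_visits", "outpatient_visits", "inpatient_discharges",
                "rx_fills", "chronic_count")) {
    bad <- panel[[col]] < 0
    if (any(bad)) bad_row_msg(col, bad, "must be non-negative")
  }
  for (col in bin_cols) {
    bad <- !panel[[col]] %in% c(0, 1)
    if (any(bad)) bad_row_msg(col, bad, "must be 0 or 1")
  }
  if (any(panel$round < 1)) {
    bad_row_msg("round", panel$round < 1, "must be >= 1")
  }
  if (any(!is.finite(panel$income) | panel$income < 0)) {
    bad_row_msg("income", !is.finite(panel$income) | panel$income < 0,
                "must be non-negative and finite")
  }
  if (any(panel$family_size < 1)) {
    bad_row_msg("family_size", panel$family_size < 1, "must be >= 1")
  }

  dup <- duplicated(panel[c("person_id", "round")])
  if (any(dup)) {
    abort(
      paste0("Duplicate (person_id, round) pair: person ",
             panel$person_id[which(dup)[1]], ", round ",
             panel$round[which(dup)[1]], "."),
      class = "medchurn_validation_error"
    )
  }

  panel <- dplyr::arrange(panel, .data$person_id, .data$round)

  T_max <- max(panel$round)
  by_person <- split(panel$round, panel$person_id)
  complete <- vapply(by_person, function(r) identical(as.integer(r),
                                                      seq_len(T_max)),
                     logical(1))
  if (!all(complete)) {
    bad_ids <- names(by_person)[!complete]
    if (drop_incomplete) {
      panel <- panel[!panel$person_id %in% bad_ids, , drop = FALSE]
      if (nrow(panel) == 0) {
        abort("All persons have incomplete round sequences.",
              class = "medchurn_validation_error")
      }
    } else {
      abort(
        paste0(length(bad_ids), " person(s) lack the complete round ",
               "sequence 1..", T_max, " (e.g. person ", bad_ids[1],
               "). Use drop_incomplete = TRUE to drop them."),
        class = "medchurn_validation_error"
      )
    }
  }

  static_cols <- c("age", "male", "married", "high_school", "white",
                   "family_size", "chronic_count")
  for (col in static_cols) {
    n_distinct <- tapply(panel[[col]], panel$person_id,
                         function(x) length(unique(x)))
    if (any(n_distinct > 1)) {
      abort(
        paste0("Time-constant covariate `", col, "` varies within person ",
               names(n_distinct)[which(n_distinct > 1)[1]], "."),
        class = "medchurn_validation_error"
      )
    }
  }

  for (col in int_cols) panel[[col]] <- as.integer(panel[[col]])
  for (col in bin_cols) panel[[col]] <- as.integer(panel[[col]])
  panel$age <- as.double(panel$age)
  panel$income <- as.double(panel$income)
  panel
}

#' Number of rounds in a validated panel
#'
#' @param panel A validated panel tibble.
#' @return The common number of rounds `T`.
#' @export
n_rounds <- function(panel) {
  if (nrow(panel) == 0) return(0L)
  max(panel$round)
}

#' Number of persons in a panel
#'
#' @param panel A validated panel tibble.
#' @return The number of unique persons.
#' @export
n_persons <- function(panel) {
  length(unique(panel$person_id))
}

#' Read a person-round panel from CSV
#'
#' Reads a comma-separated, UTF-8 file with one row per person-round and a
#' header naming the canonical schema columns:
#' `person_id, round, medicaid, employed, healthy, income, er_visits,
#' outpatient_visits, inpatient_discharges, rx_fills, age, male, married,
#' high_school, white, family_size, chronic_count`.  The file is validated
#' with [validate_panel()] before being returned.
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_panel
#' @return A validated panel tibble.
#' @export
read_panel <- function(path, drop_incomplete = FALSE) {
  spec <- readr::cols(
    person_id = readr::col_character(),
    .default = readr::col_double()
  )
  panel <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(panel_schema(), names(panel))
  if (length(missing_cols) > 0) {
    abort(
      paste0("File ", path, " is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "medchurn_schema_error"
    )
  }
  validate_panel(panel, drop_incomplete = drop_incomplete)
}

#' Write a person-round panel to CSV
#'
#' The inverse of [read_panel()]: `read_panel(write_panel(p, f))`
#' reproduces `p` exactly (numeric columns are written at full precision,
#' no quoting of numerics, "." decimal separator).
#'
#' @param panel A validated panel tibble (validated again before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}
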