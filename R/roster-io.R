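#' Read a patient roster
#'
#' Reads a CSV roster of PET/CT patients, one row per patient, grouped into
#' study sessions by `session_id`. Row order within a session is preserved:
#' it is the tie-break key used by [select_groups()] when two patients share
#' an age.
#'
#' @param path Path to a CSV file with columns `session_id`, `patient_id`,
#'   `sex` (`"M"` or `"F"`), `age` (integer years, 18--90), `weight_kg`
#'   (optional, may be missing), `activity_mbq` (administered FDG activity,
#'   positive integer MBq) and `scan_time_s` (positive integer seconds).
#'   Extra columns are ignored.
#' @return A tibble with the columns above, one row per patient, in file
#'   order.
#' @examples
#' roster <- read_roster(agedose_example("worked_session.csv"))
#' dplyr::count(roster, session_id)
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) {
    stop("roster file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("session_id", "patient_id", "sex", "age",
                "activity_mbq", "scan_time_s")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("roster is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"weight_kg" %in% names(raw)) raw$weight_kg <- NA_character_
  roster <- tibble::tibble(
    session_id   = raw$session_id,
    patient_id   = raw$patient_id,
    sex          = raw$sex,
    age          = parse_num(raw$age, "age"),
    weight_kg    = suppressWarnings(as.numeric(raw$weight_kg)),
    activity_mbq = parse_num(raw$activity_mbq, "activity_mbq"),
    scan_time_s  = parse_num(raw$scan_time_s, "scan_time_s")
  )
  validate_roster(roster)
  roster
}

# Numeric parse that names the offending row, so a bad cell in a large
# roster is findable.
parse_num <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop("non-numeric value in column '", col, "' at row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out
}

validate_roster <- function(roster) {
  if (nrow(roster) == 0) return(invisible(roster))
  if (!all(roster$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  dup <- roster |>
    dplyr::count(.data$session_id, .data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated patient_id '", dup$patient_id[1], "' in session '",
         dup$session_id[1], "'", call. = FALSE)
  }
  if (any(roster$age < 18 | roster$age > 90)) {
    stop("age outside the study range [18, 90]", call. = FALSE)
  }
  if (any(roster$activity_mbq <= 0) || any(roster$scan_time_s <= 0)) {
    stop("activity_mbq and scan_time_s must be positive", call. = FALSE)
  }
  invisible(roster)
}

#' Write and re-read per-patient evaluation results
#'
#' `write_results()` serialises the output of [evaluate_sessions()] to CSV at
#' a declared precision: activities and scan times as integers, effective
#' doses to 3 decimals, risks to 4 decimals, percent changes to 4 decimals.
#' `read_results()` reads such a file back; a write-then-read round trip is
#' lossless at that precision.
#'
#' @param results A tibble as returned by [evaluate_sessions()].
#' @param path Output (input) CSV path.
#' @return `write_results()` returns `results` invisibly; `read_results()`
#'   returns a tibble.
#' @export
write_results <- function(results, path) {
  cols <- c("session_id", "patient_id", "sex", "age", "group",
            "activity_mbq", "scan_time_s", "activity_algo_mbq",
            "scan_time_algo_s", "ed_ref_msv", "ed_algo_msv",
            "acr_ref", "acr_algo", "pct_change")
  out <- results[intersect(cols, names(results))]
  out <- dplyr::mutate(
    out,
    dplyr::across(dplyr::any_of(c("activity_mbq", "scan_time_s",
                                  "activity_algo_mbq", "scan_time_algo_s",
                                  "age")), as.integer),
    dplyr::across(dplyr::any_of(c("ed_ref_msv", "ed_algo_msv")),
                  ~ round(.x, 3)),
    dplyr::across(dplyr::any_of(c("acr_ref", "acr_algo", "pct_change")),
                  ~ round(.x, 4))
  )
  readr::write_csv(out, path)
  invisible(results)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    session_id = readr::col_character(),
                    patient_id = readr::col_character(),
                    sex = readr::col_character(),
                    group = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Bundled example data
#'
#' @description
#' The package bundles three small plain-text datasets:
#'
#' * `worked_session.csv` — an illustrative ten-patient clinical session with
#'   the reference and age-modified activity and scan time, the reference
#'   effective dose, and the additional cancer risk under both protocols, as
#'   printed in the source study session table.
#' * `session_summaries.csv` — per-session summaries (sex counts, age range,
#'   mean risk under both protocols, percent decrease) of the 43 consecutive
#'   clinical sessions of the study cohort.
#' * `calibrated_risk_table.csv` — the age- and sex-specific risk
#'   coefficients (risk per mSv) back-calculated from the worked session's
#'   printed dose and risk columns; see [default_risk_table()].
#'
#' `agedose_example()` returns the installed path of one of these files;
#' `worked_session()` and `session_summaries()` read them into tibbles.
#'
#' @param file File name within the package's `extdata` directory.
#' @return A file path, or a tibble.
#' @examples
#' worked_session()
#' @export
agedose_example <- function(file) {
  path <- system.file("extdata", file, package = "agedose", mustWork = FALSE)
  if (identical(path, "")) {
    stop("no bundled file named '", file, "'", call. = FALSE)
  }
  path
}

#' @rdname agedose_example
#' @export
worked_session <- function() {
  readr::read_csv(agedose_example("worked_session.csv"),
                  show_col_types = FALSE,
                  col_types = readr::cols(
                    session_id = readr::col_character(),
                    patient_id = readr::col_character(),
                    sex = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @rdname agedose_example
#' @export
session_summaries <- function() {
  readr::read_csv(agedose_example("session_summaries.csv"),
                  show_col_types = FALSE)
}
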