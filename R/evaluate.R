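#' Percent change between two mean risks
#'
#' `100 * (mean_ref - mean_algo) / mean_ref`: positive values are
#' reductions under the modified protocol, negative values increases. The
#' value is returned unrounded; [format_percent()] applies the
#' one-decimal truncated display convention used in the summary tables.
#'
#' @param mean_ref Reference-condition mean risk (positive).
#' @param mean_algo Modified-condition mean risk.
#' @return Percent change (vectorised).
#' @examples
#' percent_change(0.0200, 0.0187)   # 6.5
#' @export
percent_change <- function(mean_ref, mean_algo) {
  if (any(mean_ref <= 0, na.rm = TRUE)) {
    stop("reference mean must be positive", call. = FALSE)
  }
  100 * (mean_ref - mean_algo) / mean_ref
}

#' One-decimal truncated percent display
#'
#' Truncates toward zero to one decimal (7.46 displays as 7.4, -7.46 as
#' -7.4). Display only — no internal computation rounds.
#'
#' @param x Percent values.
#' @return Truncated numeric values.
#' @export
format_percent <- function(x) {
  trunc(x * 10) / 10
}

#' Paired t-test on risks under the two protocols
#'
#' Standard paired Student t on the per-patient differences
#' (`ref - algo`), `df = n - 1`, two-sided p. All-zero or zero-variance
#' differences cannot support the test: a classed warning
#' (`agedose_degenerate_t`) is raised and the statistic returned as `NA`.
#'
#' @param ref,algo Equal-length numeric vectors of per-patient risks,
#'   `n >= 2`.
#' @return A one-row tibble: `n`, `mean_diff`, `statistic`, `df`,
#'   `p.value`.
#' @examples
#' res <- evaluate_sessions(worked_session())
#' paired_t(res$acr_ref, res$acr_algo)
#' @export
paired_t <- function(ref, algo) {
  if (length(ref) != length(algo)) {
    stop("ref and algo must have equal length", call. = FALSE)
  }
  n <- length(ref)
  if (n < 2) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- ref - algo
  if (stats::sd(d) == 0) {
    warning(rlang::warning_cnd(
      class = "agedose_degenerate_t",
      message = "zero-variance differences: paired t-test is degenerate"
    ))
    return(tibble::tibble(n = n, mean_diff = mean(d),
                          statistic = NA_real_, df = n - 1,
                          p.value = NA_real_))
  }
  tt <- stats::t.test(ref, algo, paired = TRUE)
  tibble::tibble(n = n, mean_diff = mean(d),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p.value = tt$p.value)
}

acr_stratum_stats <- function(results) {
  n <- nrow(results)
  if (n == 0) {
    return(tibble::tibble(
      n = 0L, mean_acr_ref = NA_real_, sd_acr_ref = NA_real_,
      mean_acr_algo = NA_real_, sd_acr_algo = NA_real_,
      pct_change = NA_real_, statistic = NA_real_, df = NA_real_,
      p.value = NA_real_))
  }
  tt <- if (n >= 2 && stats::sd(results$acr_ref - results$acr_algo) > 0) {
    paired_t(results$acr_ref, results$acr_algo)
  } else {
    tibble::tibble(statistic = NA_real_, df = n - 1, p.value = NA_real_)
  }
  tibble::tibble(
    n = n,
    mean_acr_ref = mean(results$acr_ref),
    sd_acr_ref = stats::sd(results$acr_ref),
    mean_acr_algo = mean(results$acr_algo),
    sd_acr_algo = stats::sd(results$acr_algo),
    pct_change = percent_change(mean(results$acr_ref),
                                mean(results$acr_algo)),
    statistic = tt$statistic, df = as.numeric(tt$df), p.value = tt$p.value
  )
}

#' Stratified comparison of risk under the two protocols
#'
#' Summarises per-patient results into the study's reporting strata: the
#' whole population, each sex, and the three age brackets (18--29, 30--60,
#' 61--90). Per stratum: patient count, mean and sample (n - 1) sd of the
#' risk under both protocols, the percent change of the stratum means
#' (ratio of means, not a mean of per-patient ratios), and a paired t-test.
#' Standard deviations use single patients as the unit.
#'
#' @param results Output of [evaluate_sessions()].
#' @return A tibble of class `acr_summary`, one row per stratum (`total`,
#'   `F`, `M`, `18-29`, `30-60`, `61-90`).
#' @examples
#' worked_session() |> evaluate_sessions() |> summarize_cohort()
#' @export
summarize_cohort <- function(results) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  results$bracket <- bracket_of(results$age)
  strata <- list(
    total   = results,
    `F`     = results[results$sex == "F", ],
    M       = results[results$sex == "M", ],
    `18-29` = results[results$bracket == "18-29", ],
    `30-60` = results[results$bracket == "30-60", ],
    `61-90` = results[results$bracket == "61-90", ]
  )
  out <- purrr::map(strata, acr_stratum_stats) |>
    purrr::list_rbind(names_to = "stratum")
  class(out) <- c("acr_summary", class(tibble::tibble()))
  out
}

#' Per-session summary table
#'
#' One row per study session: sex counts, age range, mean risk under both
#' protocols and the percent decrease, computed from the unrounded session
#' means.
#'
#' @param results Output of [evaluate_sessions()].
#' @return A tibble with columns `session_id`, `n_female`, `n_male`,
#'   `age_min`, `age_max`, `mean_acr_ref`, `mean_acr_algo`,
#'   `pct_decrease`.
#' @examples
#' worked_session() |> evaluate_sessions() |> session_table()
#' @export
session_table <- function(results) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  results |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      n_female = sum(.data$sex == "F"),
      n_male = sum(.data$sex == "M"),
      age_min = min(.data$age),
      age_max = max(.data$age),
      mean_acr_ref = mean(.data$acr_ref),
      mean_acr_algo = mean(.data$acr_algo),
      pct_decrease = percent_change(.data$mean_acr_ref,
                                    .data$mean_acr_algo),
      .groups = "drop"
    )
}

#' Write a stratified summary to JSON
#'
#' @param summary An [summarize_cohort()] result.
#' @param path Output path.
#' @return `summary`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  rows <- split(dplyr::select(summary, -"stratum"), summary$stratum)
  jsonlite::write_json(purrr::map(rows, ~ as.list(.x)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
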