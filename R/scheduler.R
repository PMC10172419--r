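#' Age-based dose/time modification scheme
#'
#' The scheduling rule at the core of the package: within each study
#' session, the `k` youngest patients have their administered activity
#' reduced by the fraction `f` and their scan time lengthened by the same
#' fraction; the `k` oldest have activity raised and scan time shortened by
#' `f`; everyone else is unchanged. The counting statistic (activity x
#' time) of a modified patient scales by `(1 - f)(1 + f) = 1 - f^2`
#' (0.96 at the default `f = 0.2`), i.e. the reallocation is
#' approximately, not exactly, count-preserving.
#'
#' @param fraction Modification fraction `f` in `[0, 1)`; default 0.20.
#' @param group_size Number of patients `k` modified at each end of the age
#'   order; default 3.
#' @param truncation How fractional MBq/seconds are made integer:
#'   `"floor"` (default, matching the worked example's arithmetic) or
#'   `"round"`.
#' @param strict_min_size If `TRUE`, a session with fewer than `2k + 1`
#'   patients is an error; by default `k` is shrunk to
#'   `floor((n - 1) / 2)` with a warning.
#' @return An `algo_scheme` object (a validated list).
#' @examples
#' algo_scheme()
#' @export
algo_scheme <- function(fraction = 0.20, group_size = 3,
                        truncation = c("floor", "round"),
                        strict_min_size = FALSE) {
  truncation <- match.arg(truncation)
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  if (group_size < 0 || group_size != as.integer(group_size)) {
    stop("group_size must be a non-negative integer", call. = FALSE)
  }
  structure(list(fraction = fraction, group_size = as.integer(group_size),
                 truncation = truncation, strict_min_size = strict_min_size),
            class = "algo_scheme")
}

#' @export
print.algo_scheme <- function(x, ...) {
  cat(sprintf("age-based reallocation scheme: f = %g, k = %d, %s truncation\n",
              x$fraction, x$group_size, x$truncation))
  invisible(x)
}

#' Read a scheme from a YAML or JSON config
#'
#' Keys: `fraction` (0.20), `group_size` (3), `truncation` ("floor"),
#' `strict_min_size` (false); all optional.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [algo_scheme()].
#' @export
read_scheme_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  algo_scheme(fraction = cfg$fraction %||% 0.20,
              group_size = cfg$group_size %||% 3,
              truncation = cfg$truncation %||% "floor",
              strict_min_size = isTRUE(cfg$strict_min_size))
}

# Integer truncation of a scaled activity or scan time. The small epsilon
# guards against the binary representation of factors like 1.2 turning an
# exact product (e.g. 1165 * 1.2 = 1398) into 1397.99999... before floor().
trunc_scaled <- function(x, truncation) {
  switch(truncation,
         floor = floor(x + 1e-7),
         round = round(x))
}

#' Assign patients to young / middle / old groups within each session
#'
#' Patients are ordered by age ascending, ties broken by roster (file)
#' order; the first `k` are `young`, the last `k` are `old`, the remainder
#' `middle`. A session with fewer than `2k + 1` patients has `k` shrunk to
#' `floor((n - 1) / 2)` (with a warning) so the groups never overlap and at
#' least one patient stays unmodified.
#'
#' @param roster A roster tibble (see [read_roster()]); may hold several
#'   sessions.
#' @param k Group size at each end of the age order.
#' @param strict If `TRUE`, error instead of shrinking `k`.
#' @return The roster with a `group` column (`"young"`/`"middle"`/`"old"`),
#'   original row order preserved.
#' @examples
#' select_groups(read_roster(agedose_example("worked_session.csv")), k = 3)
#' @export
select_groups <- function(roster, k = 3, strict = FALSE) {
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  if (nrow(roster) == 0) stop("empty roster", call. = FALSE)
  roster |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      k_eff <- k
      if (n < 2 * k + 1) {
        if (strict) {
          stop("session '", key$session_id, "' has ", n,
               " patients, fewer than 2k + 1 = ", 2 * k + 1, call. = FALSE)
        }
        k_eff <- (n - 1) %/% 2
        warning("session '", key$session_id, "': shrinking k from ", k,
                " to ", k_eff, " (only ", n, " patients)", call. = FALSE)
      }
      ord <- order(df$age)  # stable: ties keep roster order
      grp <- rep("middle", n)
      if (k_eff > 0) {
        grp[ord[seq_len(k_eff)]] <- "young"
        grp[ord[seq(n - k_eff + 1, n)]] <- "old"
      }
      df$group <- grp
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row") |>
    dplyr::relocate("session_id")
}

#' Apply the age-based reallocation to a roster
#'
#' Adds the modified acquisition plan: for `young` patients
#' `activity' = trunc(activity * (1 - f))` and
#' `scan_time' = trunc(scan_time * (1 + f))`; for `old` patients the
#' factors are swapped; `middle` patients keep their reference plan. All
#' outputs are positive integers.
#'
#' @param roster A roster tibble; may hold several sessions.
#' @param scheme An [algo_scheme()].
#' @return The roster with columns `group`, `activity_algo_mbq`,
#'   `scan_time_algo_s` added. Patient count, identities and row order are
#'   unchanged.
#' @examples
#' read_roster(agedose_example("worked_session.csv")) |> apply_algo()
#' @export
apply_algo <- function(roster, scheme = algo_scheme()) {
  stopifnot(inherits(scheme, "algo_scheme"))
  f <- scheme$fraction
  planned <- select_groups(roster, k = scheme$group_size,
                           strict = scheme$strict_min_size)
  fac_act <- dplyr::case_match(planned$group,
                               "young" ~ 1 - f, "old" ~ 1 + f, "middle" ~ 1)
  fac_time <- dplyr::case_match(planned$group,
                                "young" ~ 1 + f, "old" ~ 1 - f, "middle" ~ 1)
  planned$activity_algo_mbq <- ifelse(
    planned$group == "middle", planned$activity_mbq,
    trunc_scaled(planned$activity_mbq * fac_act, scheme$truncation))
  planned$scan_time_algo_s <- ifelse(
    planned$group == "middle", planned$scan_time_s,
    trunc_scaled(planned$scan_time_s * fac_time, scheme$truncation))
  if (any(planned$activity_algo_mbq < 1) || any(planned$scan_time_algo_s < 1)) {
    stop("scheme drives an activity or scan time to zero", call. = FALSE)
  }
  planned
}

#' Evaluate dose and risk under the reference and modified plans
#'
#' Attaches per-patient effective dose and additional cancer risk under
#' both conditions, and the per-patient percent risk change
#' `100 * (ACR_ref - ACR_algo) / ACR_ref` (positive = reduction). The
#' modified-plan dose uses the truncated integer activity. Because the risk
#' model is linear in dose, `acr_algo / acr_ref` equals the activity ratio
#' exactly for every patient.
#'
#' @param planned Output of [apply_algo()] (a roster may also be passed; the
#'   scheme default is then applied first).
#' @param coefficient A [ed_coefficient()] or bare number, mSv/MBq.
#' @param table A [risk_table()].
#' @param scheme Scheme used if `planned` lacks a modified plan.
#' @return A tibble with `ed_ref_msv`, `ed_algo_msv`, `acr_ref`,
#'   `acr_algo` and `pct_change` columns added, of class `algo_results`.
#' @examples
#' read_roster(agedose_example("worked_session.csv")) |>
#'   apply_algo() |>
#'   evaluate_sessions()
#' @export
evaluate_sessions <- function(planned,
                              coefficient = ed_coefficient(),
                              table = default_risk_table(),
                              scheme = algo_scheme()) {
  needed <- c("group", "activity_algo_mbq", "scan_time_algo_s")
  if (!all(needed %in% names(planned))) {
    planned <- apply_algo(planned, scheme)
  }
  out <- planned |>
    dplyr::mutate(
      ed_ref_msv  = effective_dose(.data$activity_mbq, coefficient),
      ed_algo_msv = effective_dose(.data$activity_algo_mbq, coefficient),
      acr_ref  = acr(.data$ed_ref_msv, .data$age, .data$sex, table),
      acr_algo = acr(.data$ed_algo_msv, .data$age, .data$sex, table),
      pct_change = 100 * (.data$acr_ref - .data$acr_algo) / .data$acr_ref
    )
  class(out) <- c("algo_results", class(tibble::tibble()))
  out
}
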