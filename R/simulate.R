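#' Synthetic-cohort configuration
#'
#' Defaults reproduce the published structure of the study population:
#' 43 sessions of 7--13 patients (mean 9.8), 57% male, age 64 +/- 14 years
#' truncated to \[18, 90\], weight 72.3 +/- 14.2 kg, activity prescribed at
#' 3.95 MBq/kg and clipped to the administered range \[185, 399\] MBq, scan
#' time 1191 +/- 198 s. The per-kg activity spread (sd 0.3 MBq/kg) and the
#' weight truncation bounds are package choices — the study reports only
#' means, sds and ranges — and are exposed as knobs. Age and sex are drawn
#' independently; the real sessions' age clustering is not emulated.
#'
#' @param n_sessions Number of sessions.
#' @param session_size_range Inclusive integer range of per-session patient
#'   counts, drawn uniformly.
#' @param p_male Probability a patient is male.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param weight_mean,weight_sd,weight_range Truncated-normal weight model
#'   (kg).
#' @param activity_per_kg_mean,activity_per_kg_sd Normal per-kg prescription
#'   (MBq/kg); the resulting activity is floored to an integer and clipped
#'   to `activity_range`.
#' @param activity_range Administered-activity bounds (MBq).
#' @param scan_time_mean,scan_time_sd,scan_time_range Normal scan-time model
#'   (s), clipped and floored.
#' @return A `cohort_config` object (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_sessions = 43,
                          session_size_range = c(7, 13),
                          p_male = 0.57,
                          age_mean = 64, age_sd = 14, age_range = c(18, 90),
                          weight_mean = 72.3, weight_sd = 14.2,
                          weight_range = c(40, 120),
                          activity_per_kg_mean = 3.95,
                          activity_per_kg_sd = 0.3,
                          activity_range = c(185, 399),
                          scan_time_mean = 1191, scan_time_sd = 198,
                          scan_time_range = c(600, 1800)) {
  cfg <- list(n_sessions = n_sessions,
              session_size_range = session_size_range,
              p_male = p_male,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              weight_mean = weight_mean, weight_sd = weight_sd,
              weight_range = weight_range,
              activity_per_kg_mean = activity_per_kg_mean,
              activity_per_kg_sd = activity_per_kg_sd,
              activity_range = activity_range,
              scan_time_mean = scan_time_mean, scan_time_sd = scan_time_sd,
              scan_time_range = scan_time_range)
  for (nm in c("session_size_range", "age_range", "weight_range",
               "activity_range", "scan_time_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(nm, " must be an ordered length-2 range", call. = FALSE)
    }
  }
  if (p_male < 0 || p_male > 1) stop("p_male must be in [0, 1]", call. = FALSE)
  if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Inverse-CDF truncated-normal sampler: map uniforms into the CDF mass
# between the bounds. Deterministic given the RNG state.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic cohort of PET sessions
#'
#' Draws a seeded roster with the demographic and protocol structure
#' described in [cohort_config()]. Every generated patient satisfies the
#' roster invariants (age in \[18, 90\], positive integer activity and scan
#' time); activity is `floor(weight * per-kg draw)` clipped to the
#' administered range.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed yields the identical cohort. If
#'   `NULL`, the current RNG state is used.
#' @return A roster tibble (see [read_roster()]) with sessions `S01`,
#'   `S02`, ... and patients `S01-P01`, ...
#' @examples
#' roster <- generate_cohort(seed = 1)
#' nrow(roster)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sizes <- sample(seq(config$session_size_range[1],
                      config$session_size_range[2]),
                  config$n_sessions, replace = TRUE)
  n <- sum(sizes)
  age <- round(rtruncnorm(n, config$age_mean, config$age_sd,
                          config$age_range[1], config$age_range[2]))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  weight <- rtruncnorm(n, config$weight_mean, config$weight_sd,
                       config$weight_range[1], config$weight_range[2])
  activity <- floor(weight * stats::rnorm(n, config$activity_per_kg_mean,
                                          config$activity_per_kg_sd))
  activity <- pmin(pmax(activity, config$activity_range[1]),
                   config$activity_range[2])
  scan_time <- floor(stats::rnorm(n, config$scan_time_mean,
                                  config$scan_time_sd))
  scan_time <- pmin(pmax(scan_time, config$scan_time_range[1]),
                    config$scan_time_range[2])
  session_id <- rep(sprintf("S%02d", seq_len(config$n_sessions)), sizes)
  tibble::tibble(
    session_id = session_id,
    patient_id = paste0(session_id, "-P",
                        sprintf("%02d", unlist(lapply(sizes, seq_len)))),
    sex = ifelse(stats::runif(n) < config$p_male, "M", "F"),
    age = age,
    weight_kg = round(weight, 1),
    activity_mbq = activity,
    scan_time_s = scan_time
  )
}

#' Age bracket of a patient
#'
#' The study's three inclusive age strata: 18--29, 30--60 and 61--90 years.
#'
#' @param age Ages in years, each within \[18, 90\].
#' @return A factor with levels `"18-29"`, `"30-60"`, `"61-90"`.
#' @examples
#' bracket_of(c(29, 30, 64))
#' @export
bracket_of <- function(age) {
  if (any(age < 18 | age > 90, na.rm = TRUE)) {
    stop("age outside [18, 90]", call. = FALSE)
  }
  cut(age, breaks = c(17, 29, 60, 90),
      labels = c("18-29", "30-60", "61-90"))
}
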