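#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects. `tidy()` on an
#' `acr_summary` returns the per-stratum table (one row per stratum);
#' `glance()` returns the single whole-population row. `tidy()` on an
#' `algo_results` tibble returns the per-patient rows with the key model
#' columns first.
#'
#' @param x An `acr_summary` or `algo_results` object.
#' @param ... Unused.
#' @return A tibble.
#' @name agedose-tidiers
NULL

#' @rdname agedose-tidiers
#' @exportS3Method generics::tidy
tidy.acr_summary <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname agedose-tidiers
#' @exportS3Method generics::glance
glance.acr_summary <- function(x, ...) {
  out <- x[x$stratum == "total", ]
  class(out) <- class(tibble::tibble())
  dplyr::rename(out, n_patients = "n")[, c(
    "n_patients", "mean_acr_ref", "mean_acr_algo", "pct_change",
    "statistic", "df", "p.value")]
}

#' @rdname agedose-tidiers
#' @exportS3Method generics::tidy
tidy.algo_results <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  dplyr::relocate(out, "session_id", "patient_id", "sex", "age", "group",
                  "acr_ref", "acr_algo", "pct_change")
}

#' @rdname agedose-tidiers
#' @exportS3Method generics::glance
glance.algo_results <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x),
    n_sessions = dplyr::n_distinct(x$session_id),
    mean_acr_ref = mean(x$acr_ref),
    mean_acr_algo = mean(x$acr_algo),
    pct_change = percent_change(mean(x$acr_ref), mean(x$acr_algo))
  )
}
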