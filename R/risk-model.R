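#' Age- and sex-indexed risk-coefficient table
#'
#' The additional cancer risk (ACR) of a scan is modelled as linear in
#' effective dose with an age- and sex-specific slope:
#' `ACR = r(age, sex) * ED`. A `risk_table` holds the tabulated slopes
#' (risk per mSv) together with an interpolation policy for ages between
#' tabulated nodes and an extrapolation policy outside the tabulated range.
#'
#' Coefficients are expected to decrease with age at exposure within each
#' sex (younger patients carry more lifetime risk per unit dose); a
#' violation is reported as a warning, not an error, because a user-supplied
#' lifetable-derived table can legitimately wiggle.
#'
#' @param entries A data frame with columns `sex` (`"M"`/`"F"`), `age`
#'   (years) and `coefficient_per_msv` (positive). Ages must be strictly
#'   increasing within each sex.
#' @param interpolation `"linear"` (piecewise-linear in age, the default) or
#'   `"nearest"`.
#' @param extrapolation `"clamp"` (use the nearest end value outside the
#'   tabulated range, the default) or `"error"`.
#' @return A `risk_table`: a tibble of entries sorted by sex then age, with
#'   the two policies stored as attributes.
#' @seealso [default_risk_table()], [calibrate_risk_table()],
#'   [coefficient_at()], [acr()]
#' @export
risk_table <- function(entries,
                       interpolation = c("linear", "nearest"),
                       extrapolation = c("clamp", "error")) {
  interpolation <- match.arg(interpolation)
  extrapolation <- match.arg(extrapolation)
  stopifnot(is.data.frame(entries),
            all(c("sex", "age", "coefficient_per_msv") %in% names(entries)))
  if (nrow(entries) == 0) stop("risk table needs at least one entry", call. = FALSE)
  if (!all(entries$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (any(entries$coefficient_per_msv <= 0)) {
    stop("all risk coefficients must be positive", call. = FALSE)
  }
  entries <- entries |>
    tibble::as_tibble() |>
    dplyr::select("sex", "age", "coefficient_per_msv") |>
    dplyr::arrange(.data$sex, .data$age)
  dup <- entries |>
    dplyr::count(.data$sex, .data$age) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate age ", dup$age[1], " for sex ", dup$sex[1], call. = FALSE)
  }
  nonmono <- entries |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(ok = all(diff(.data$coefficient_per_msv) <= 0),
                     .groups = "drop")
  if (!all(nonmono$ok)) {
    warning("risk coefficients are not non-increasing with age for sex ",
            paste(nonmono$sex[!nonmono$ok], collapse = ", "), call. = FALSE)
  }
  structure(entries,
            interpolation = interpolation,
            extrapolation = extrapolation,
            class = c("risk_table", class(entries)))
}

#' Read a risk-coefficient table from CSV
#'
#' @param path CSV with columns `sex`, `age`, `coefficient_per_msv`.
#' @inheritParams risk_table
#' @return A [risk_table()].
#' @export
read_risk_table <- function(path,
                            interpolation = c("linear", "nearest"),
                            extrapolation = c("clamp", "error")) {
  risk_table(readr::read_csv(path, show_col_types = FALSE),
             interpolation = match.arg(interpolation),
             extrapolation = match.arg(extrapolation))
}

#' Default calibrated risk table
#'
#' The coefficients back-calculated from the bundled worked-example session:
#' one node per patient, `coefficient = ACR / ED` from the printed reference
#' columns. They decrease with age within each sex and are higher for
#' females than for males at comparable ages, the qualitative structure of
#' BEIR VII lifetime-attributable-risk tables. These calibrated values are
#' the package's only link to the source study's (undisclosed) risk model,
#' and reports should retain that provenance.
#'
#' @return A [risk_table()] with 10 entries (male nodes at ages 19, 51, 63,
#'   76, 77, 79; female nodes at 29, 67, 70, 81).
#' @examples
#' default_risk_table()
#' @export
default_risk_table <- function() {
  read_risk_table(agedose_example("calibrated_risk_table.csv"))
}

#' Look up a risk coefficient
#'
#' Returns the risk-per-mSv slope at the given ages and sexes under the
#' table's interpolation policy: exact node values at tabulated ages,
#' piecewise-linear (or nearest-node) interpolation between nodes, and
#' clamping to the end values outside the tabulated range (or an error,
#' per the table's extrapolation policy).
#'
#' @param table A [risk_table()].
#' @param age Ages in years (vectorised).
#' @param sex `"M"`/`"F"`, recycled against `age`.
#' @return Risk coefficients per mSv.
#' @examples
#' coefficient_at(default_risk_table(), 51, "M")
#' @export
coefficient_at <- function(table, age, sex) {
  stopifnot(inherits(table, "risk_table"))
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  for (s in unique(sex)) {
    sub <- table[table$sex == s, ]
    if (nrow(sub) == 0) {
      stop("risk table has no entries for sex '", s, "'", call. = FALSE)
    }
    idx <- which(sex == s)
    a <- age[idx]
    if (identical(attr(table, "extrapolation"), "error") &&
        any(a < min(sub$age) | a > max(sub$age))) {
      stop("age outside the tabulated range [", min(sub$age), ", ",
           max(sub$age), "] for sex ", s, call. = FALSE)
    }
    a_cl <- pmin(pmax(a, min(sub$age)), max(sub$age))
    if (identical(attr(table, "interpolation"), "nearest")) {
      near <- vapply(a_cl, function(x) which.min(abs(sub$age - x)), integer(1))
      out[idx] <- sub$coefficient_per_msv[near]
    } else if (nrow(sub) == 1) {
      out[idx] <- sub$coefficient_per_msv
    } else {
      out[idx] <- stats::approx(sub$age, sub$coefficient_per_msv,
                                xout = a_cl, method = "linear")$y
    }
  }
  out
}

#' Additional cancer risk of an effective dose
#'
#' `ACR = r(age, sex) * ED`: strictly linear in dose, so the ratio of two
#' risks for the same patient equals the ratio of the administered
#' activities. The risk is reported on the calibration scale of the table
#' in use (for the default table, the source study's printed scale, e.g.
#' 0.0687 for a 19-year-old male at 5.792 mSv) without asserting whether
#' that scale is percent or per-person.
#'
#' @param ed_msv Effective dose in mSv (vectorised, non-negative).
#' @param age,sex Patient age(s) and sex(es), recycled to a common length.
#' @param table A [risk_table()]; defaults to the calibrated table.
#' @return Additional cancer risk, same length as the inputs.
#' @examples
#' acr(4.528, 51, "M")   # 0.0223
#' @export
acr <- function(ed_msv, age, sex, table = default_risk_table()) {
  if (any(ed_msv < 0, na.rm = TRUE)) {
    stop("effective dose must be non-negative", call. = FALSE)
  }
  coefficient_at(table, age, sex) * ed_msv
}

#' Calibrate a risk table from observed dose/risk pairs
#'
#' Inverts the linear risk model on observations: each (ED, ACR, age, sex)
#' observation becomes one table node with `coefficient = ACR / ED`.
#' Applying [acr()] back at the same ages and doses reproduces the observed
#' risks exactly.
#'
#' @param observations A data frame with columns `ed_msv` (positive), `acr`,
#'   `age`, `sex`; at most one observation per (age, sex).
#' @inheritParams risk_table
#' @return A [risk_table()] with one entry per observation.
#' @examples
#' ws <- worked_session()
#' calibrate_risk_table(
#'   dplyr::transmute(ws, ed_msv = ed_ref_msv, acr = acr_ref, age, sex)
#' )
#' @export
calibrate_risk_table <- function(observations,
                                 interpolation = c("linear", "nearest"),
                                 extrapolation = c("clamp", "error")) {
  stopifnot(is.data.frame(observations),
            all(c("ed_msv", "acr", "age", "sex") %in% names(observations)))
  if (any(observations$ed_msv <= 0)) {
    stop("all effective doses must be positive", call. = FALSE)
  }
  risk_table(
    dplyr::transmute(observations,
                     sex = .data$sex, age = .data$age,
                     coefficient_per_msv = .data$acr / .data$ed_msv),
    interpolation = match.arg(interpolation),
    extrapolation = match.arg(extrapolation)
  )
}
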