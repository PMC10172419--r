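#' Plot a stratified risk comparison
#'
#' Bar chart of the percent risk change by stratum: bars above zero are
#' reductions under the modified protocol, below zero increases.
#'
#' @param object An `acr_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' worked_session() |>
#'   evaluate_sessions() |>
#'   summarize_cohort() |>
#'   ggplot2::autoplot()
#' @exportS3Method ggplot2::autoplot
autoplot.acr_summary <- function(object, ...) {
  df <- tidy.acr_summary(object)
  df$stratum <- factor(df$stratum, levels = df$stratum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$pct_change,
                                   fill = .data$pct_change > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#d95f0e")) +
    ggplot2::labs(x = NULL, y = "risk reduction vs reference (%)",
                  title = "Age-based reallocation: risk change by stratum") +
    ggplot2::theme_minimal()
}

#' Plot per-patient risk under both protocols
#'
#' Paired dot plot over the age axis: each patient's additional cancer
#' risk under the reference and modified protocols, coloured by
#' reallocation group.
#'
#' @param object An `algo_results` tibble from [evaluate_sessions()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.algo_results <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy.algo_results(object),
                            c("acr_ref", "acr_algo"),
                            names_to = "condition", values_to = "acr_value")
  df$condition <- factor(df$condition, levels = c("acr_ref", "acr_algo"),
                         labels = c("reference", "modified"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$acr_value,
                                   colour = .data$group,
                                   shape = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "age at exposure (y)", y = "additional cancer risk",
                  colour = "group", shape = "protocol") +
    ggplot2::theme_minimal()
}

#' Plot per-session mean risks
#'
#' Session-level view of the cohort: mean risk under both protocols for
#' every study session, joined by a segment whose direction shows whether
#' the session's mean risk fell or rose.
#'
#' @param sessions Output of [session_table()].
#' @return A ggplot.
#' @export
plot_session_risk <- function(sessions) {
  df <- tidyr::pivot_longer(sessions, c("mean_acr_ref", "mean_acr_algo"),
                            names_to = "condition", values_to = "mean_acr")
  df$condition <- factor(df$condition,
                         levels = c("mean_acr_ref", "mean_acr_algo"),
                         labels = c("reference", "modified"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session_id, y = .data$mean_acr,
                                   colour = .data$condition,
                                   group = .data$session_id)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = "session", y = "mean additional cancer risk",
                  colour = "protocol") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
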