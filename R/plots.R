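# ggplot2 presentations of the three result types: the rotation scatter
# (body vs head angle, symbol = contact call), the state-by-contact summary
# table, and the replicate frameshift summaries.

#' @method autoplot survey_records
#' @export
autoplot.survey_records <- function(object, ...) {
  dat <- fig_scatter(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$body_angle, y = .data$head_angle,
    shape = .data$call)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(
      intercalated = 15, stacked = 0, retracted = 1, unresolved = 4)) +
    ggplot2::labs(
      x = "30S body rotation (deg)", y = "30S head rotation (deg)",
      shape = "A1503 contact",
      title = "Query-base contact by ribosome rotational state"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot survey_table
#' @export
autoplot.survey_table <- function(object, ...) {
  long <- object |>
    select("state", "n_intercalated", "n_stacked", "n_retracted") |>
    tidyr::pivot_longer(-"state", names_to = "call", values_to = "n",
      names_prefix = "n_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$n,
    fill = .data$call)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "structures", fill = "contact",
      title = "A1503 contact class by conformational state") +
    ggplot2::theme_minimal()
}

#' @method autoplot fs_summary
#' @export
autoplot.fs_summary <- function(object, metric = c("ratio_fs", "percent_fs",
                                  "activity"), ...) {
  metric <- match.arg(metric)
  m <- paste0("mean_", metric)
  s <- paste0("sem_", metric)
  if (!m %in% names(object)) {
    abort(sprintf("summary has no %s column", m),
      class = "riboframe_validation_error")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$construct, y = .data[[m]])) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
      ymax = .data[[m]] + .data[[s]]), width = 0.25) +
    ggplot2::labs(x = NULL, y = switch(metric,
      ratio_fs = "-1 / 0-frame product ratio",
      percent_fs = "% -1 frameshift",
      activity = "activity (fraction of control)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
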