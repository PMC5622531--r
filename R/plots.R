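# ggplot2 views of the three result types: the literature panel, the
# prevalence table and the source-attribution split.

#' @describeIn rank_comorbidities Bar chart of co-occurrence counts,
#'   rank-ordered.
#' @param object A `comorbidity_panel`.
#' @method autoplot comorbidity_panel
#' @export
autoplot.comorbidity_panel <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$dui, .data$count),
                                   y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Co-occurring citations",
                  title = sprintf("Top comorbidity panel of %s",
                                  attr(object, "index_dui"))) +
    ggplot2::theme_minimal()
}

#' @describeIn prevalence_ci Forest plot of per-1000 prevalences with
#'   their intervals; Wilson rows are marked.
#' @param object A `prevalence_estimate`.
#' @method autoplot prevalence_estimate
#' @export
autoplot.prevalence_estimate <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- if ("name" %in% names(df) && !all(is.na(df$name))) df$name else df$dui
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$p_per_1000),
                                   y = .data$p_per_1000)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low_per_1000,
                                          ymax = .data$ci_high_per_1000,
                                          shape = .data$method)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Prevalence per 1000 patients",
                  shape = "CI method") +
    ggplot2::theme_minimal()
}

#' Stacked source-attribution plot
#'
#' Per-disease stacked percentages of cases found by text alone, by
#' structured sources (ICD codes and/or drug prescriptions) alone, or by
#' both.
#'
#' @param attribution Tibble from [attribute_sources()].
#' @param names Optional tibble (`dui`, `name`) for display labels.
#' @return A ggplot object.
#' @export
plot_source_attribution <- function(attribution, names = NULL) {
  df <- filter(attribution, .data$n_total > 0)
  if (!is.null(names)) {
    df <- left_join(df, names, by = "dui")
    df$dui <- ifelse(is.na(df$name), df$dui, df$name)
  }
  long <- tidyr::pivot_longer(
    df, c("pct_text_only", "pct_structured_only", "pct_both"),
    names_to = "source", values_to = "pct") |>
    mutate(source = factor(.data$source,
                           levels = c("pct_text_only", "pct_both",
                                      "pct_structured_only"),
                           labels = c("Text only", "Both",
                                      "Structured only")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dui, y = .data$pct,
                                     fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_grey(start = 0.1, end = 0.8) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of detected cases", fill = NULL) +
    ggplot2::theme_minimal()
}
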