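# ggplot2 views of the result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.geometry_report <- function(object, ...) {
  rec <- tidy(object)
  cut_df <- tibble::tibble(
    kind = names(object$cutoffs),
    cutoff = as.numeric(object$cutoffs)
  )
  ggplot2::ggplot(rec, ggplot2::aes(
    x = .data$atoms, y = .data$abs_delta, fill = .data$is_outlier
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      data = cut_df[cut_df$kind %in% rec$kind, ],
      ggplot2::aes(yintercept = .data$cutoff), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"), guide = "none"
    ) +
    ggplot2::labs(
      x = NULL, y = "|target - actual|",
      title = sprintf("Deviations from restraint targets (%s)", object$comp_id)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.qmr_binned_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin, y = .data$mean, colour = .data$condition,
    group = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sem,
        ymax = .data$mean + .data$sem
      ),
      width = 0.2
    ) +
    ggplot2::labs(
      x = "resolution bin (Å)", y = "mean r.m.s.d.",
      colour = "restraints"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.qmr_result <- function(object, ...) {
  rec <- tidy(object)
  ggplot2::ggplot(rec, ggplot2::aes(
    x = .data$condition, y = .data$abs_delta, colour = .data$kind
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "|target - actual|",
      title = "Restraint deviations before (base) and after (in-situ)"
    ) +
    ggplot2::theme_minimal()
}
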