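# ggplot2 visualisations for the main result types.

#' Plot per-species fold-changes by lipid class
#'
#' One jittered point per lipid species with a crossbar at the class
#' total-mass fold-change, on a log scale around the no-change line at 1 —
#' the conventional class-scatter view of a lipidomics comparison.
#'
#' @param fold_changes Output of [compute_fold_changes()] (one or several
#'   comparisons bound together).
#' @return A ggplot object, faceted by comparison when several are present.
#' @export
#' @examples
#' profiles <- lipid_sim_config(seed = 1) |>
#'   simulate_peak_table() |>
#'   peaks_to_profiles()
#' plot_class_fold_changes(compute_fold_changes(profiles, "KO"))
plot_class_fold_changes <- function(fold_changes) {
  assert_columns(fold_changes,
                 c("class", "comparison", "fold_change",
                   "mean_numerator", "mean_denominator"),
                 "fold_changes")
  totals <- summarize_class(fold_changes)
  p <- ggplot2::ggplot(fold_changes,
                       ggplot2::aes(x = .data$class, y = .data$fold_change)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_crossbar(
      data = totals,
      ggplot2::aes(y = .data$total_mass_fold_change,
                   ymin = .data$total_mass_fold_change,
                   ymax = .data$total_mass_fold_change),
      width = 0.6, colour = "firebrick", linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Lipid class", y = "Fold-change (log scale)",
                  caption = "points: species; bar: total-mass fold-change") +
    ggplot2::theme_minimal()
  if (length(unique(fold_changes$comparison)) > 1) {
    p <- p + ggplot2::facet_wrap(~comparison)
  }
  p
}

#' Autoplot method for lipid class test results
#'
#' Median class fold-changes with the per-species scatter (when the
#' fold-change table is attached) and significance markers above each
#' class.
#'
#' @param object A `lipid_class_tests` object from [test_lipid_classes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lipid_class_tests
#' @export
autoplot.lipid_class_tests <- function(object, ...) {
  fcs <- attr(object, "fold_changes")
  res <- tidy(object)
  p <- if (!is.null(fcs)) {
    plot_class_fold_changes(fcs)
  } else {
    ggplot2::ggplot(res, ggplot2::aes(x = .data$class,
                                      y = .data$median_fold_change)) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "Lipid class", y = "Median fold-change") +
      ggplot2::theme_minimal() +
      ggplot2::facet_wrap(~comparison)
  }
  marks <- res[!is.na(res$marker) & res$marker != "", ]
  if (nrow(marks) > 0) {
    ymax <- max(c(fcs$fold_change, res$median_fold_change), na.rm = TRUE)
    marks$y <- ymax * 1.3
    p <- p + ggplot2::geom_text(
      data = marks,
      ggplot2::aes(x = .data$class, y = .data$y, label = .data$marker),
      inherit.aes = FALSE, size = 3)
  }
  p
}

#' Autoplot method for group comparisons
#'
#' Jittered per-animal values by group with the group means, annotated with
#' the ANOVA p-value.
#'
#' @param object A `group_comparison` object from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  means <- dplyr::summarise(dplyr::group_by(object$data, .data$group),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_crossbar(
      data = means,
      ggplot2::aes(ymin = .data$value, ymax = .data$value),
      width = 0.5, colour = "firebrick", linewidth = 0.4) +
    ggplot2::labs(
      x = NULL, y = object$value_label,
      subtitle = sprintf("one-way ANOVA p = %.4g", object$anova$p_value)) +
    ggplot2::theme_minimal()
}
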