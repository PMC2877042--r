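# ggplot2 views of the result tables.

#' Plot the positional profile of log2(PM/MM)
#'
#' Line of the per-position median with a ribbon spanning median +/- MAD,
#' and the pair count mapped to point size.
#'
#' @param profile A [position_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_position_profile <- function(profile) {
  assert_data_frame(profile, "profile", c("position", "n", "median", "mad"))
  pts <- dplyr::filter(profile, .data$n > 0L)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$position, y = .data$median)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$median - .data$mad, ymax = .data$median + .data$mad),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "steelblue") +
    ggplot2::scale_size_continuous(name = "pairs") +
    ggplot2::labs(
      x = "mismatch position on the probe (1 = 5' end)",
      y = expression(log[2](PM / MM[i])),
      title = "Mismatch effect by probe position"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.xsmm_spread_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$median, y = .data$mad)) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "grey40", linetype = 2
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$position), size = 3) +
    ggplot2::labs(
      x = "median log2(PM/MM) at position",
      y = "MAD of log2(PM/MM) at position",
      title = sprintf("Spread vs location (R² = %.2f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean effects per mismatch type and position group
#'
#' Grouped bars of the mean log2(PM/MM) for the 5' / center / 3' groups of
#' each mismatch type, the types ordered by pair class.
#'
#' @param summary A [type_group_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_type_group_summary <- function(summary) {
  assert_data_frame(summary, "summary", c(
    "mismatch_type", "mean_five_prime", "mean_center", "mean_three_prime"
  ))
  long <- summary %>%
    tidyr::pivot_longer(
      dplyr::all_of(c("mean_five_prime", "mean_center", "mean_three_prime")),
      names_to = "group", values_to = "mean_log2_ratio"
    ) %>%
    dplyr::mutate(
      group = factor(.data$group,
        levels = c("mean_five_prime", "mean_center", "mean_three_prime"),
        labels = c("5' end (1-8)", "center (9-17)", "3' end (18-25)")
      ),
      mismatch_type = factor(.data$mismatch_type, levels = mismatch_types())
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$mismatch_type, y = .data$mean_log2_ratio, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "position group") +
    ggplot2::labs(
      x = "mismatch type (PM base - MM base)",
      y = expression(mean ~ log[2](PM / MM)),
      title = "Mismatch effect by type and position group"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-study correlations
#'
#' @param report A [correlate_studies()] tibble.
#' @param metric Which coefficient to tile: `"spearman"` or `"pearson"`.
#' @return A ggplot object.
#' @export
plot_study_correlation <- function(report, metric = c("spearman", "pearson")) {
  metric <- match.arg(metric)
  assert_data_frame(report, "report", c("study_a", "study_b"))
  col <- if (metric == "spearman") "spearman_rho" else "pearson_r"
  ggplot2::ggplot(report, ggplot2::aes(
    x = .data$study_a, y = .data$study_b, fill = .data[[col]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data[[col]])),
      size = 3
    ) +
    ggplot2::scale_fill_gradient2(
      limits = c(-1, 1), low = "indianred", high = "steelblue", name = metric
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Cross-study agreement (12 mismatch types)") +
    ggplot2::theme_minimal()
}
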