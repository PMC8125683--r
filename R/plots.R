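#' Plot benchmark aggregates across cutoffs
#'
#' Grouped bars of the three pipeline metrics (average indication accuracy,
#' pairwise accuracy, coverage percent) at every cutoff, for one result or
#' several.
#'
#' @param object A `benchmark_result`.
#' @param ... Further `benchmark_result` objects to overlay.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_result <- function(object, ...) {
  extra <- purrr::keep(list(...), ~ inherits(.x, "benchmark_result"))
  long <- purrr::map(c(list(object), extra), glance) %>%
    bind_rows() %>%
    select(-"coverage_count") %>%
    tidyr::pivot_longer(
      c("average_indication_accuracy", "pairwise_accuracy", "coverage_percent"),
      names_to = "metric", values_to = "value"
    ) %>%
    mutate(cutoff = factor(sprintf("top%d", .data$cutoff),
                           levels = sprintf("top%d", sort(unique(.data$cutoff)))))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cutoff, y = .data$value, fill = .data$pipeline_label
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "rank cutoff", y = "percent", fill = "pipeline") +
    ggplot2::theme_minimal()
}

#' Scatter of paired per-indication accuracies for two pipelines
#'
#' @param res_a,res_b `benchmark_result` objects over the same indications.
#' @param k Cutoff.
#' @return A ggplot object; points on the diagonal are indications both
#'   pipelines score identically.
#' @export
plot_accuracy_scatter <- function(res_a, res_b, k) {
  paired <- paired_accuracies(res_a, res_b, k)
  ggplot2::ggplot(paired, ggplot2::aes(
    x = .data$acc_a, y = .data$acc_b, size = .data$d
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(
      x = paste0(res_a$pipeline_label, " accuracy (%)"),
      y = paste0(res_b$pipeline_label, " accuracy (%)"),
      size = "approved drugs", title = sprintf("top%d", as.integer(k))
    ) +
    ggplot2::theme_minimal()
}

#' Tornado plot of per-indication net accuracy differences
#'
#' @inheritParams plot_accuracy_scatter
#' @return A ggplot object; bars right of zero favour pipeline A.
#' @export
plot_net_difference <- function(res_a, res_b, k) {
  tab <- net_difference_table(res_a, res_b, k) %>%
    mutate(indication_id = factor(.data$indication_id,
                                  levels = rev(.data$indication_id)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$diff, y = .data$indication_id)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = paste0("accuracy difference (%, ", res_a$pipeline_label, " - ",
                 res_b$pipeline_label, ")"),
      y = "indication (descending approved-drug count)"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of drug-indication pair ranks under two pipelines
#'
#' @param consensus A tibble from [pair_rank_consensus()].
#' @param log_scale Use log10 axes (default `TRUE`); rank densities span
#'   orders of magnitude on realistic libraries.
#' @return A ggplot object.
#' @export
plot_pair_ranks <- function(consensus, log_scale = TRUE) {
  p <- ggplot2::ggplot(consensus, ggplot2::aes(
    x = .data$rank_a, y = .data$rank_b
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "best co-drug rank, pipeline A",
                  y = "best co-drug rank, pipeline B") +
    ggplot2::theme_minimal()
  if (log_scale) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Histogram overlay of per-indication accuracy distributions
#'
#' @inheritParams plot_accuracy_scatter
#' @param binwidth Accuracy bin width in percent (default 10).
#' @return A ggplot object annotated with the KS comparison.
#' @export
plot_accuracy_histogram <- function(res_a, res_b, k, binwidth = 10) {
  paired <- paired_accuracies(res_a, res_b, k)
  ks <- ks_compare(paired$acc_a, paired$acc_b)
  long <- tibble(
    pipeline = rep(c(res_a$pipeline_label, res_b$pipeline_label),
                   each = nrow(paired)),
    accuracy = c(paired$acc_a, paired$acc_b)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$accuracy, fill = .data$pipeline)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "dodge") +
    ggplot2::labs(
      x = "indication accuracy (%)", y = "indications",
      subtitle = sprintf("KS D = %.3f, p = %.3g", ks$statistic, ks$p_value)
    ) +
    ggplot2::theme_minimal()
}
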