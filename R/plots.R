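#' Bar chart of top-feature prediction quality per model
#'
#' Mirrors the usual way cross-omics benchmarks are reported: one bar per
#' model with the mean Spearman correlation of the top-k predicted
#' features, error bar = mean per-feature SD across splits.
#'
#' @param result A `benchmark_result`, or a named list of `feature_scores`.
#' @return A ggplot object.
#' @export
plot_feature_scores <- function(result) {
  fs <- if (inherits(result, "benchmark_result")) result$feature_scores else result
  df <- dplyr::bind_rows(lapply(names(fs), function(m) {
    s <- attr(fs[[m]], "summary")
    tibble::tibble(model = m, score = s$score, error = s$error, top_k = s$top_k)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$score - .data$error,
                                        ymax = .data$score + .data$error), width = 0.15) +
    ggplot2::labs(x = NULL, y = sprintf("mean Spearman (top %d features)", df$top_k[1])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.feature_scores <- function(object, k = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), k)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean - .data$sd,
                                         xmax = .data$mean + .data$sd), height = 0.3) +
    ggplot2::labs(x = "mean Spearman across splits", y = NULL) +
    ggplot2::theme_minimal()
}

#' Density comparison of input-vs-truth and predicted-vs-truth correlations
#'
#' @param shift Result of [correlation_shift_densities()].
#' @return A ggplot object.
#' @export
plot_correlation_densities <- function(shift) {
  long <- tidyr::pivot_longer(shift, c("input_vs_truth", "predicted_vs_truth"),
                              names_to = "comparison", values_to = "correlation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$correlation, fill = .data$comparison)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "Spearman correlation with ground truth", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.core_set_report <- function(object, ...) {
  df <- tidy.core_set_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_a, y = .data$set_b, fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$jaccard)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Balanced accuracy of IBD classifiers by data source
#'
#' @param runs Tibble from [run_ibd_classification()].
#' @return A ggplot object.
#' @export
plot_classification <- function(runs) {
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$source, y = .data$balanced_accuracy)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "balanced accuracy") +
    ggplot2::theme_minimal()
}
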