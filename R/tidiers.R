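#' Tidy a cross-validation report
#'
#' @param x An `stt_cv` report from [run_cv()].
#' @param ... Unused.
#' @return Tibble with one row per fold and logit head: `fold`, `head`,
#'   `n_test`, `sensitivity`, `specificity`, `accuracy`.
#' @export
tidy.stt_cv <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation report
#'
#' @param x An `stt_cv` report.
#' @param ... Unused.
#' @return One-row tibble with the fold-averaged metrics of the report's
#'   evaluation head, plus `k` and `n_groups`.
#' @export
glance.stt_cv <- function(x, ...) {
  agg <- x$aggregate[x$aggregate$head == x$eval_head, ]
  tibble::tibble(sensitivity = agg$sensitivity,
                 specificity = agg$specificity,
                 accuracy = agg$accuracy,
                 k = length(x$fold_sizes),
                 n_groups = sum(x$fold_sizes))
}

#' Per-fold metric spread of a cross-validation run
#'
#' @param object An `stt_cv` report.
#' @param head Logit head to display.
#' @param ... Unused.
#' @return A ggplot: metrics on the x axis, per-fold values as points with
#'   the fold mean marked.
#' @export
autoplot.stt_cv <- function(object, head = object$eval_head, ...) {
  df <- tidyr::pivot_longer(
    object$per_fold[object$per_fold$head == head, ],
    c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, color = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("Cross-validated metrics (%s head)", head)) +
    ggplot2::theme_minimal()
}

#' Bar chart of the channel ablation
#'
#' @param object An `stt_ablation` table from [ablation_channels()].
#' @param ... Unused.
#' @return A ggplot comparing sensitivity, specificity and accuracy across
#'   the spatial, temporal and combined variants.
#' @export
autoplot.stt_ablation <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("sensitivity", "specificity", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Single-stream vs combined model") +
    ggplot2::theme_minimal()
}

#' Heatmap of the heads-by-layers grid
#'
#' @param object An `stt_grid` table from [ablation_grid()].
#' @param ... Unused.
#' @return A ggplot tile map of accuracy over the swept grid.
#' @export
autoplot.stt_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$n_heads),
                               y = factor(.data$n_layers),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$accuracy)), color = "white") +
    ggplot2::labs(x = "attention heads", y = "encoder layers",
                  title = "Accuracy over the heads-by-layers grid") +
    ggplot2::theme_minimal()
}

#' Loss-weight sweep curve
#'
#' @param object An `stt_alpha_sweep` table from [sweep_alpha()].
#' @param ... Unused.
#' @return A ggplot of accuracy against the spatial-stream loss weight.
#' @export
autoplot.stt_alpha_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "accuracy",
                  title = "Composite-loss weight sweep") +
    ggplot2::theme_minimal()
}
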