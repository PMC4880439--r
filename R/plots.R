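#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline geom_abline labs facet_wrap theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot a calibration curve
#'
#' Raw and smoothed per-bin deleterious fractions against the bin centers,
#' with the decision threshold marked.
#'
#' @param object A [fit_confidence_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$center)) +
    geom_point(aes(y = .data$frac_deleterious), alpha = 0.4) +
    geom_line(aes(y = .data$smoothed_frac_deleterious), linewidth = 0.8) +
    geom_vline(xintercept = object$threshold, linetype = "dashed") +
    labs(
      title = sprintf("Calibration curve: %s / %s", object$tool, object$category),
      x = "raw score (bin center)",
      y = "fraction deleterious (points: raw, line: smoothed)"
    ) +
    theme_minimal()
}

#' Plot per-tool, per-category decision thresholds and training accuracy
#'
#' @param object A [fit_thresholds()] object.
#' @param ... Unused.
#' @return A ggplot of training normalized accuracy per tool, faceted by
#'   category.
#' @export
autoplot.threshold_model <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$tool, y = .data$train_normalized_accuracy)) +
    geom_col() +
    facet_wrap(~category) +
    labs(x = NULL, y = "training normalized accuracy") +
    theme_minimal()
}

#' Plot a metrics report
#'
#' Grouped bars of a chosen metric per predictor, faceted by category — the
#' usual tool-comparison figure.
#'
#' @param object An [evaluate_model()] tibble.
#' @param metric Column to plot (default `"normalized_accuracy"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metrics_report <- function(object, metric = "normalized_accuracy", ...) {
  df <- dplyr::filter(object, .data$aggregation == "category")
  ggplot(df, aes(x = .data$predictor, y = .data[[metric]])) +
    geom_col(position = position_dodge()) +
    facet_wrap(~category) +
    labs(x = NULL, y = metric) +
    theme_minimal()
}

#' Class-conditional score distributions per tool and category
#'
#' Density view of deleterious vs neutral raw scores, the picture that
#' motivates category-specific thresholds.
#'
#' @param data Labeled score tibble (`label`, `category`, tool columns).
#' @param tools Tool columns to include (default: attached specs).
#' @return A ggplot faceted by tool x category.
#' @export
plot_score_distributions <- function(data, tools = NULL) {
  if (is.null(tools)) tools <- get_tool_specs(data)$tool
  long <- tidyr::pivot_longer(data, dplyr::all_of(tools),
                              names_to = "tool", values_to = "score")
  ggplot(long, aes(x = .data$score, colour = .data$label)) +
    ggplot2::geom_density() +
    ggplot2::facet_grid(tool ~ category, scales = "free") +
    labs(x = "raw score", y = "density", colour = NULL) +
    theme_minimal()
}

#' Reliability diagram for predictions
#'
#' Bins predictions by stated confidence and plots the empirical accuracy of
#' each bin against its mean confidence; a calibrated predictor tracks the
#' diagonal.
#'
#' @param preds A [predict_variants()] tibble.
#' @param labels True labels aligned with `preds` rows.
#' @param n_groups Number of confidence bins (default 10).
#' @return A ggplot.
#' @export
plot_reliability <- function(preds, labels, n_groups = 10) {
  df <- reliability_table(preds$consensus_prediction,
                          preds$consensus_confidence, labels, n_groups)
  ggplot(df, aes(x = .data$mean_confidence / 100, y = .data$accuracy)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_point(aes(size = .data$n)) +
    geom_line() +
    labs(x = "mean stated confidence", y = "empirical accuracy") +
    theme_minimal()
}

#' Per-confidence-bin calibration table
#'
#' @param prediction,confidence Prediction (`"D"`/`"N"`) and confidence
#'   (0-99) vectors.
#' @param labels True labels.
#' @param n_groups Number of equal-count confidence groups (default 10).
#' @return A tibble: `group`, `n`, `mean_confidence`, `accuracy`. Tied
#'   confidence values always land in the same group, so fewer than
#'   `n_groups` groups may be returned when the confidence scale is coarse.
#' @export
reliability_table <- function(prediction, confidence, labels, n_groups = 10) {
  is_d <- as_deleterious(labels)
  ok <- !is.na(prediction)
  correct <- (prediction[ok] == "D") == is_d[ok]
  conf <- confidence[ok]
  # quantile breaks keep tied confidences together; splitting ties by row
  # order would create groups correlated with the input ordering, not with
  # the stated confidence
  breaks <- unique(stats::quantile(conf, probs = seq(0, 1, length.out = n_groups + 1),
                                   type = 1, names = FALSE))
  grp <- if (length(breaks) < 2) rep(1L, length(conf)) else
    as.integer(cut(conf, breaks = breaks, include.lowest = TRUE))
  tibble(group = grp, confidence = conf, correct = correct) %>%
    group_by(.data$group) %>%
    summarize(n = dplyr::n(), mean_confidence = mean(.data$confidence),
              accuracy = mean(.data$correct), .groups = "drop")
}
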