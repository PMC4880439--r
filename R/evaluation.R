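#' Confusion-matrix metrics for binary predictions
#'
#' Computes accuracy, sensitivity, specificity, normalized (balanced)
#' accuracy and the Matthews correlation coefficient from `"D"`/`"N"`
#' predictions against deleterious/neutral labels. Predictions that are `NA`
#' (e.g. variants missing the tool's score) are excluded from the counts and
#' reported as `n_missing`, so `tp+fp+tn+fn+n_missing` always equals the
#' input size. Sub-metrics undefined for the observed counts are `NA`.
#'
#' @param predictions Character vector `"D"`/`"N"` (NA allowed).
#' @param labels Labels (`"deleterious"`/`"neutral"` or `"D"`/`"N"`).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `n_missing`, `accuracy`,
#'   `sensitivity`, `specificity`, `normalized_accuracy`, `mcc`.
#' @export
confusion_metrics <- function(predictions, labels) {
  is_d <- as_deleterious(labels)
  if (length(predictions) != length(is_d)) abort("predictions and labels differ in length")
  if (length(predictions) == 0) abort("need at least one labeled prediction")
  miss <- is.na(predictions)
  p <- predictions[!miss] == "D"
  y <- is_d[!miss]
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n_missing = sum(miss),
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    sensitivity = sens, specificity = spec,
    normalized_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    mcc = mcc
  )
}

#' Area under the ROC curve
#'
#' Rank (Mann–Whitney) formulation: the probability that a random deleterious
#' variant outscores a random neutral one, with ties credited one half —
#' identical to the trapezoidal area under the ROC curve, in O(n log n).
#'
#' @param scores Numeric scores (finite; drop missing upstream).
#' @param labels Labels.
#' @param polarity Tool polarity; under `lower_is_deleterious` scores are
#'   negated before ranking.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels,
                    polarity = c("higher_is_deleterious",
                                 "lower_is_deleterious")) {
  polarity <- match.arg(polarity)
  is_d <- as_deleterious(labels)
  if (any(!is.finite(scores))) abort("scores must be finite")
  if (all(is_d) || !any(is_d)) abort("both classes must be present for AUC")
  s <- if (polarity == "higher_is_deleterious") scores else -scores
  r <- rank(s)  # average ranks handle ties as half-credit
  n_d <- sum(is_d)
  n_n <- sum(!is_d)
  (sum(r[is_d]) - n_d * (n_d + 1) / 2) / (n_d * n_n)
}

#' Pairwise Spearman correlation of raw tool scores
#'
#' Rank correlation between every pair of tool-score columns over
#' pairwise-complete variants; entries backed by fewer than 3 complete pairs
#' are `NA`. Used to quantify how redundant the integrated tools are within
#' a category.
#'
#' @param scores Score table (or any tibble with the tool columns).
#' @param tools Character vector of tool columns; defaults to the attached
#'   tool specs.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pairwise_spearman <- function(scores, tools = NULL) {
  if (is.null(tools)) tools <- get_tool_specs(scores)$tool
  m <- as.matrix(scores[, tools, drop = FALSE])
  out <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  )
  for (i in seq_along(tools)) {
    for (j in seq_along(tools)) {
      n_ok <- sum(stats::complete.cases(m[, c(i, j)]))
      if (n_ok < 3) out[i, j] <- NA_real_
    }
  }
  diag(out) <- 1
  out
}

#' Pairwise prediction agreement between tools
#'
#' For every pair of tools, over the variants both predicted, the fractions
#' of cases where both were correct, both wrong, or they disagreed (the
#' three sum to 1).
#'
#' @param predictions Tibble (or matrix) of `"D"`/`"N"` predictions, one
#'   column per tool; `NA` = not predicted.
#' @param labels Labels, one per row.
#' @return A tibble with columns `tool_a`, `tool_b`, `n`, `both_correct`,
#'   `both_wrong`, `discordant` (fractions `NA` when no co-predicted
#'   variants).
#' @export
agreement_matrix <- function(predictions, labels) {
  is_d <- as_deleterious(labels)
  m <- as.matrix(predictions)
  tools <- colnames(m)
  truth <- ifelse(is_d, "D", "N")
  pairs <- utils::combn(tools, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    a <- m[, pr[1]]; b <- m[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n == 0) {
      return(tibble(tool_a = pr[1], tool_b = pr[2], n = 0L,
                    both_correct = NA_real_, both_wrong = NA_real_,
                    discordant = NA_real_))
    }
    ca <- a[ok] == truth[ok]
    cb <- b[ok] == truth[ok]
    tibble(tool_a = pr[1], tool_b = pr[2], n = n,
           both_correct = mean(ca & cb),
           both_wrong = mean(!ca & !cb),
           discordant = mean(ca != cb))
  }) |> bind_rows()
}

#' Category-optimal versus general threshold comparison
#'
#' Evaluates the same scores under a category-specific threshold and under a
#' single pooled ("general") threshold learned on category-agnostic training
#' data, returning both normalized accuracies and their difference — the
#' quantity behind the argument for categorizing variants before
#' thresholding.
#'
#' @param scores,labels Evaluation data for one category.
#' @param general_threshold,category_threshold Decision thresholds.
#' @param polarity Tool polarity.
#' @return One-row tibble: `na_general`, `na_category`, `gain`.
#' @export
compare_thresholds <- function(scores, labels, general_threshold,
                               category_threshold,
                               polarity = c("higher_is_deleterious",
                                            "lower_is_deleterious")) {
  polarity <- match.arg(polarity)
  na_of <- function(thr) {
    confusion_metrics(apply_threshold(scores, thr, polarity), labels)$normalized_accuracy
  }
  g <- na_of(general_threshold)
  cth <- na_of(category_threshold)
  tibble(na_general = g, na_category = cth, gain = cth - g)
}

#' Per-tool and consensus performance report
#'
#' Applies a trained bundle to a labeled evaluation set and tabulates, per
#' category and overall, the confusion metrics and AUC for every tool and
#' for the consensus. Variants missing a tool's score are excluded from that
#' tool's counts (reported under `n_missing`). The `"overall"` rows are
#' emitted in both aggregations: micro (pooled counts across categories) and
#' macro (unweighted mean of per-category metrics), labeled in the
#' `aggregation` column.
#'
#' @param data Labeled tibble: `label`, `category`, one score column per tool.
#' @param bundle A [train_model()] bundle.
#' @param split Optional split label echoed in the output.
#' @return A `metrics_report` tibble: `predictor`, `category`, `split`,
#'   `aggregation`, the [confusion_metrics()] columns and `auc`.
#' @export
evaluate_model <- function(data, bundle, split = NA_character_) {
  stopifnot(inherits(bundle, "model_bundle"))
  specs <- bundle$specs
  cats <- intersect(names(bundle$consensus), unique(data$category))
  rows <- list()
  per_cat_preds <- list()
  for (cat in cats) {
    sub <- data[data$category == cat, ]
    cm <- bundle$consensus[[cat]]
    for (tl in specs$tool) {
      cv <- bundle$thresholds$curves[[curve_key(tl, cat)]]
      if (is.null(cv)) next
      tr <- transform_score(cv, sub[[tl]])
      met <- confusion_metrics(tr$prediction, sub$label)
      ok <- !is.na(sub[[tl]])
      auc <- if (length(unique(as_deleterious(sub$label[ok]))) == 2) {
        roc_auc(sub[[tl]][ok], sub$label[ok],
                specs$polarity[specs$tool == tl])
      } else NA_real_
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(predictor = tl, category = cat, split = split,
               aggregation = "category"), met, tibble(auc = auc))
    }
    votes <- vote_matrices(sub, cm$tools, bundle$thresholds, cat)
    cs <- consensus_scores_matrix(votes$pred, votes$conf)
    tr <- transform_score(cm$curve, cs)
    met <- confusion_metrics(tr$prediction, sub$label)
    ok <- !is.na(cs)
    auc <- if (length(unique(as_deleterious(sub$label[ok]))) == 2) {
      roc_auc(cs[ok], sub$label[ok], "higher_is_deleterious")
    } else NA_real_
    rows[[length(rows) + 1]] <- bind_cols(
      tibble(predictor = "consensus", category = cat, split = split,
             aggregation = "category"), met, tibble(auc = auc))
    per_cat_preds[[cat]] <- mutate(tibble(prediction = tr$prediction,
                                          label = sub$label), predictor = "consensus")
  }
  out <- bind_rows(rows)
  overall <- out %>%
    group_by(.data$predictor) %>%
    summarize(
      category = "overall", split = split[1], aggregation = "micro",
      tp = sum(.data$tp), fp = sum(.data$fp), tn = sum(.data$tn),
      fn = sum(.data$fn), n_missing = sum(.data$n_missing),
      accuracy = (sum(.data$tp) + sum(.data$tn)) /
        pmax(1, sum(.data$tp + .data$fp + .data$tn + .data$fn)),
      sensitivity = sum(.data$tp) / pmax(1, sum(.data$tp + .data$fn)),
      specificity = sum(.data$tn) / pmax(1, sum(.data$tn + .data$fp)),
      normalized_accuracy = (sensitivity + specificity) / 2,
      mcc = NA_real_, auc = NA_real_, .groups = "drop"
    )
  macro <- out %>%
    group_by(.data$predictor) %>%
    summarize(
      category = "overall", split = split[1], aggregation = "macro",
      tp = sum(.data$tp), fp = sum(.data$fp), tn = sum(.data$tn),
      fn = sum(.data$fn), n_missing = sum(.data$n_missing),
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      specificity = mean(.data$specificity, na.rm = TRUE),
      normalized_accuracy = mean(.data$normalized_accuracy, na.rm = TRUE),
      mcc = mean(.data$mcc, na.rm = TRUE),
      auc = mean(.data$auc, na.rm = TRUE), .groups = "drop"
    )
  res <- bind_rows(out, overall, macro)
  class(res) <- c("metrics_report", class(res))
  res
}
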