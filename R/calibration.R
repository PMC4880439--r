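#' Normalized (balanced) accuracy from confusion counts
#'
#' The mean of sensitivity and specificity,
#' \eqn{(tp/(tp+fn) + tn/(tn+fp))/2}. Robust to class imbalance and the
#' objective maximized by the threshold learner. Undefined when either class
#' is absent.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Balanced accuracy in \[0, 1\].
#' @export
normalized_accuracy <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) abort("confusion counts must be non-negative")
  if (tp + fn < 1 || tn + fp < 1) {
    abort("normalized accuracy undefined: one class has no observations")
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# Convert raw labels ("deleterious"/"neutral" or "D"/"N") to logical is-D.
as_deleterious <- function(labels) {
  lab <- as.character(labels)
  out <- dplyr::case_when(
    lab %in% c("deleterious", "D") ~ TRUE,
    lab %in% c("neutral", "N") ~ FALSE,
    TRUE ~ NA
  )
  if (anyNA(out)) abort("labels must be 'deleterious'/'neutral' (or 'D'/'N')")
  out
}

#' Learn the decision threshold maximizing normalized accuracy
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores, plus one candidate below the minimum and one above the maximum
#' score. The prediction rule is deleterious iff score >= threshold for
#' `higher_is_deleterious` polarity (score <= threshold when mirrored).
#' Among thresholds tied on normalized accuracy the one giving the higher
#' sensitivity wins (the lower threshold under `higher_is_deleterious`, the
#' higher one under the mirrored polarity).
#'
#' @param scores Numeric raw scores (finite; exclude missing upstream).
#' @param labels Labels, `"deleterious"`/`"neutral"` (or `"D"`/`"N"`).
#' @param polarity Tool polarity (see [tool_spec()]).
#' @return A list with `threshold` and `normalized_accuracy`.
#' @export
optimize_threshold <- function(scores, labels,
                               polarity = c("higher_is_deleterious",
                                            "lower_is_deleterious")) {
  polarity <- match.arg(polarity)
  is_d <- as_deleterious(labels)
  if (length(scores) != length(is_d)) abort("scores and labels differ in length")
  if (any(!is.finite(scores))) abort("scores must be finite; drop missing scores first")
  if (all(is_d) || !any(is_d)) abort("both classes must be present to optimize a threshold")

  # Work on an oriented scale where larger means more deleterious, then map
  # the winning threshold back.
  s <- if (polarity == "higher_is_deleterious") scores else -scores
  ord <- order(s)
  s_sorted <- s[ord]
  d_sorted <- is_d[ord]
  u <- unique(s_sorted)
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)

  n_d <- sum(d_sorted)
  n_n <- length(d_sorted) - n_d
  # Cumulative class counts at or below each candidate: predictions are D for
  # scores >= threshold, so points strictly below the candidate are called N.
  idx <- findInterval(cand, s_sorted)   # number of sorted scores <= candidate
  cum_d <- cumsum(d_sorted)
  cum_n <- cumsum(!d_sorted)
  below_d <- c(0, cum_d)[idx + 1]
  below_n <- c(0, cum_n)[idx + 1]
  tp <- n_d - below_d
  fp <- n_n - below_n
  fn <- below_d
  tn <- below_n
  na_vals <- (tp / n_d + tn / n_n) / 2

  best <- max(na_vals)
  # candidates are ascending; the first tie has the lowest oriented threshold,
  # i.e. the highest sensitivity
  pick <- which(na_vals == best)[1]
  thr <- cand[pick]
  if (polarity == "lower_is_deleterious") thr <- -thr
  list(threshold = thr, normalized_accuracy = best)
}

#' Apply a decision threshold
#'
#' @param scores Numeric scores (may contain `NA`).
#' @param threshold Decision threshold on the raw scale.
#' @param polarity Tool polarity.
#' @return Character vector `"D"`/`"N"` (`NA` propagated).
#' @export
apply_threshold <- function(scores, threshold,
                            polarity = c("higher_is_deleterious",
                                         "lower_is_deleterious")) {
  polarity <- match.arg(polarity)
  del <- if (polarity == "higher_is_deleterious") scores >= threshold
         else scores <= threshold
  ifelse(del, "D", "N")
}

#' Fit a binned observed-accuracy confidence curve
#'
#' Training points are sorted by raw score and partitioned into `n_bins` bins
#' of (as nearly as possible) equal size; per-bin fractions of deleterious
#' labels are then smoothed with a centered moving average of width `window`,
#' truncated symmetrically at the edges. The defaults (66 bins, window 11)
#' target large training sets; for small n the effective bin count is reduced
#' to `min(n_bins, floor(n/2))` so each bin holds at least two points, with
#' any remainder points distributed one per bin from the lowest bin upwards.
#'
#' @param scores Numeric raw scores (finite).
#' @param labels Labels (`"deleterious"`/`"neutral"` or `"D"`/`"N"`).
#' @param threshold The tool-by-category decision threshold.
#' @param polarity Tool polarity.
#' @param n_bins Maximum number of bins (default 66).
#' @param window Smoothing window in bins (default 11; should be odd).
#' @param tool,category Optional names stored on the curve.
#' @return An object of class `calibration_curve`: a list with `bin_edges`,
#'   `bin_centers`, `frac_deleterious` (raw), `smoothed_frac_deleterious`,
#'   `bin_n`, `threshold`, `polarity`, `n_bins`, `window`, `tool`, `category`.
#' @export
fit_confidence_curve <- function(scores, labels, threshold,
                                 polarity = c("higher_is_deleterious",
                                              "lower_is_deleterious"),
                                 n_bins = 66, window = 11,
                                 tool = NA_character_,
                                 category = NA_character_) {
  polarity <- match.arg(polarity)
  is_d <- as_deleterious(labels)
  if (any(!is.finite(scores))) abort("scores must be finite")
  n <- length(scores)
  if (n < 4) abort("confidence curve undefined for fewer than 4 training points")
  if (all(is_d) || !any(is_d)) abort("both classes must be present")
  if (length(unique(scores)) < 2) {
    abort("scores are constant; cannot fit a confidence curve")
  }

  ord <- order(scores)
  s <- scores[ord]
  d <- is_d[ord]

  b <- max(1L, min(as.integer(n_bins), n %/% 2L))
  base <- n %/% b
  rem <- n - base * b
  sizes <- rep(base, b)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin_id <- rep(seq_len(b), times = sizes)

  centers <- as.numeric(tapply(s, bin_id, mean))
  frac <- as.numeric(tapply(d, bin_id, mean))
  bin_n <- as.integer(tapply(d, bin_id, length))
  # edges: boundaries between consecutive bins (midpoint of the flanking
  # scores), plus the outer data extremes
  last_of_bin <- cumsum(sizes)
  inner <- if (b > 1) (s[last_of_bin[-b]] + s[last_of_bin[-b] + 1]) / 2 else numeric()
  edges <- c(s[1], inner, s[n])

  smoothed <- smooth_truncated(frac, window)

  structure(
    list(
      tool = tool, category = category,
      bin_edges = edges, bin_centers = centers,
      frac_deleterious = frac,
      smoothed_frac_deleterious = smoothed,
      bin_n = bin_n,
      threshold = threshold, polarity = polarity,
      n_bins = b, window = as.integer(window)
    ),
    class = "calibration_curve"
  )
}

# Centered moving average with the window truncated symmetrically at the
# edges: at bin i the half-width is min((window-1)/2, i-1, B-i).
smooth_truncated <- function(x, window) {
  b <- length(x)
  h_max <- (window - 1) %/% 2
  vapply(seq_len(b), function(i) {
    h <- min(h_max, i - 1L, b - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> tool=%s category=%s bins=%d window=%d threshold=%.4g (%s)\n",
              x$tool, x$category, x$n_bins, x$window, x$threshold, x$polarity))
  invisible(x)
}

# Interpolate the smoothed fraction-deleterious at query scores: linear
# between bin centers, clamped to the outermost bin values beyond them.
interp_frac <- function(curve, raw) {
  cx <- curve$bin_centers
  cy <- curve$smoothed_frac_deleterious
  ux <- unique(cx)
  if (length(ux) < 2) {
    return(rep(mean(cy), length(raw)))
  }
  stats::approx(cx, cy, xout = raw, rule = 2, ties = mean)$y
}

#' Transform a raw score into a prediction and a 0-99 confidence
#'
#' The binary prediction comes from the threshold rule; the confidence is the
#' side-specific observed accuracy at the query score: the smoothed training
#' fraction of deleterious labels there (for a deleterious call) or its
#' complement (for a neutral call), interpolated linearly between bin centers
#' and clamped to the outermost bin beyond the training range, then mapped to
#' an integer `min(99, round(100 * accuracy))` so the scale runs 0-99.
#'
#' @param curve A fitted [fit_confidence_curve()] object.
#' @param raw Numeric raw scores (may contain `NA`).
#' @return A tibble with columns `prediction` (`"D"`/`"N"`, `NA` for missing
#'   scores) and `confidence` (integer 0-99, `NA` for missing scores).
#' @export
transform_score <- function(curve, raw) {
  stopifnot(inherits(curve, "calibration_curve"))
  pred <- apply_threshold(raw, curve$threshold, curve$polarity)
  frac <- interp_frac(curve, raw)
  acc <- ifelse(pred == "D", frac, 1 - frac)
  conf <- pmin(99L, as.integer(round(100 * acc)))
  conf[is.na(raw)] <- NA_integer_
  pred[is.na(raw)] <- NA_character_
  tibble(prediction = pred, confidence = conf)
}

#' Train thresholds and confidence curves for every tool-by-category pair
#'
#' The per-tool, per-category learner behind the ensemble: for each tool and
#' category it drops variants missing that tool's score, learns the decision
#' threshold maximizing normalized accuracy on the training labels, and fits
#' the binned confidence curve at that threshold.
#'
#' @param train Tibble of labeled training variants with `label`, `category`
#'   and one score column per tool.
#' @param specs Tool specs.
#' @param n_bins,window Curve parameters (see [fit_confidence_curve()]).
#' @return An object of class `threshold_model`: list with `entries` (tibble
#'   tool, category, polarity, threshold, train_normalized_accuracy, n_used)
#'   and `curves` (named list of `calibration_curve`, keys `"tool|category"`).
#' @export
fit_thresholds <- function(train, specs, n_bins = 66, window = 11) {
  validate_tool_specs(specs)
  if (!all(c("label", "category") %in% names(train))) {
    abort("training data needs `label` and `category` columns")
  }
  combos <- tidyr::expand_grid(tool = specs$tool,
                               category = unique(train$category))
  curves <- list()
  rows <- purrr::pmap(combos, function(tool, category) {
    pol <- specs$polarity[specs$tool == tool]
    sub <- train[train$category == category & !is.na(train[[tool]]), ]
    opt <- optimize_threshold(sub[[tool]], sub$label, pol)
    cv <- fit_confidence_curve(sub[[tool]], sub$label, opt$threshold, pol,
                               n_bins = n_bins, window = window,
                               tool = tool, category = category)
    curves[[paste(tool, category, sep = "|")]] <<- cv
    tibble(tool = tool, category = category, polarity = pol,
           threshold = opt$threshold,
           train_normalized_accuracy = opt$normalized_accuracy,
           n_used = nrow(sub))
  })
  structure(
    list(entries = bind_rows(rows), curves = curves,
         n_bins = n_bins, window = window),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %d tool x category entries\n", nrow(x$entries)))
  print(x$entries, ...)
  invisible(x)
}

curve_key <- function(tool, category) paste(tool, category, sep = "|")

get_curve <- function(model, tool, category) {
  cv <- model$curves[[curve_key(tool, category)]]
  if (is.null(cv)) {
    abort(sprintf("no calibration curve for tool %s, category %s", tool, category))
  }
  cv
}
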