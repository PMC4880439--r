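#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a threshold model
#'
#' @param x A [fit_thresholds()] object.
#' @param ... Unused.
#' @return The entries tibble: one row per tool x category with `polarity`,
#'   `threshold`, `train_normalized_accuracy` and `n_used`.
#' @export
tidy.threshold_model <- function(x, ...) x$entries

#' @rdname tidy.threshold_model
#' @export
glance.threshold_model <- function(x, ...) {
  tibble(
    n_entries = nrow(x$entries),
    n_tools = dplyr::n_distinct(x$entries$tool),
    n_categories = dplyr::n_distinct(x$entries$category),
    n_bins = x$n_bins, window = x$window,
    mean_train_normalized_accuracy = mean(x$entries$train_normalized_accuracy)
  )
}

#' Tidy a calibration curve
#'
#' @param x A [fit_confidence_curve()] object.
#' @param ... Unused.
#' @return One row per bin: `bin`, `center`, `n`, `frac_deleterious`,
#'   `smoothed_frac_deleterious`.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(
    tool = x$tool, category = x$category,
    bin = seq_along(x$bin_centers), center = x$bin_centers, n = x$bin_n,
    frac_deleterious = x$frac_deleterious,
    smoothed_frac_deleterious = x$smoothed_frac_deleterious
  )
}

#' @rdname tidy.calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(tool = x$tool, category = x$category, n_bins = x$n_bins,
         window = x$window, threshold = x$threshold, polarity = x$polarity,
         n_train = sum(x$bin_n))
}

#' Tidy a per-category consensus model
#'
#' @param x A [select_consensus_subset()] object.
#' @param ... Unused.
#' @return The subset scan tibble (all evaluated tool subsets with their
#'   training normalized accuracy), with a `selected` flag; or a one-row
#'   summary when the model was trained without subset selection.
#' @export
tidy.consensus_model <- function(x, ...) {
  sel <- paste(x$tools, collapse = "+")
  if (is.null(x$subset_scan)) {
    return(tibble(tools = sel, size = length(x$tools),
                  normalized_accuracy = x$train_normalized_accuracy,
                  selected = TRUE))
  }
  mutate(x$subset_scan, selected = .data$tools == sel)
}

#' @rdname tidy.consensus_model
#' @export
glance.consensus_model <- function(x, ...) {
  tibble(
    category = x$category, tools = paste(x$tools, collapse = "+"),
    n_tools = length(x$tools), threshold = x$threshold,
    train_normalized_accuracy = x$train_normalized_accuracy,
    best_single_tool = x$best_single$tool %||% NA_character_,
    best_single_normalized_accuracy = x$best_single$normalized_accuracy %||% NA_real_
  )
}

#' Tidy a trained bundle
#'
#' @param x A [train_model()] bundle.
#' @param ... Unused.
#' @return Per tool x category threshold rows plus one consensus row per
#'   category (tool = `"consensus"`).
#' @export
tidy.model_bundle <- function(x, ...) {
  cons <- purrr::map(x$consensus, function(cm) {
    tibble(tool = "consensus", category = cm$category,
           polarity = "higher_is_deleterious", threshold = cm$threshold,
           train_normalized_accuracy = cm$train_normalized_accuracy,
           n_used = NA_integer_)
  }) |> bind_rows()
  bind_rows(x$thresholds$entries, cons)
}

#' @rdname tidy.model_bundle
#' @export
glance.model_bundle <- function(x, ...) {
  tibble(
    n_tools = nrow(x$specs),
    n_categories = length(x$consensus),
    n_bins = x$metadata$n_bins, window = x$metadata$window,
    select_subsets = isTRUE(x$metadata$select_subsets),
    seed = x$metadata$seed
  )
}
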