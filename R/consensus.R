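#' Confidence-weighted majority vote
#'
#' Each tool votes +1 (deleterious) or -1 (neutral), weighted by its
#' confidence/100; the consensus score is the weighted mean of the votes,
#' \eqn{\sum w_i v_i / \sum w_i}, so it always lies in \[-1, +1\] regardless
#' of how many tools contributed (0/0 is defined as 0). The consensus call is
#' deleterious iff the score is >= 0 (ties go to deleterious — the
#' conservative choice for a screening tool).
#'
#' @param prediction Character vector of votes, `"D"`/`"N"` (`NA` allowed and
#'   ignored together with its confidence).
#' @param confidence Integer confidences 0-99, same length.
#' @return A list with `score` (in \[-1, 1\]) and `prediction` (`"D"`/`"N"`).
#' @export
consensus_score <- function(prediction, confidence) {
  keep <- !is.na(prediction) & !is.na(confidence)
  prediction <- prediction[keep]
  confidence <- confidence[keep]
  if (length(prediction) == 0) abort("consensus_score requires at least one vote")
  if (any(confidence < 0)) abort("confidences must be non-negative")
  if (!all(prediction %in% c("D", "N"))) abort("votes must be 'D' or 'N'")
  v <- ifelse(prediction == "D", 1, -1)
  w <- confidence / 100
  sw <- sum(w)
  score <- if (sw == 0) 0 else sum(w * v) / sw
  list(score = score, prediction = if (score >= 0) "D" else "N")
}

# Consensus scores for a whole table of per-tool votes.
# preds: named list (per tool) of tibbles with prediction/confidence columns,
# all of equal length. Returns a numeric vector of consensus scores.
consensus_scores_matrix <- function(pred_mat, conf_mat) {
  v <- ifelse(pred_mat == "D", 1, ifelse(pred_mat == "N", -1, NA_real_))
  w <- conf_mat / 100
  w[is.na(v)] <- NA_real_
  num <- rowSums(w * v, na.rm = TRUE)
  den <- rowSums(w, na.rm = TRUE)
  any_vote <- rowSums(!is.na(v)) > 0
  out <- ifelse(den == 0, 0, num / den)
  out[!any_vote] <- NA_real_
  out
}

# Build per-tool vote matrices for one category from a labeled score table
# and a fitted threshold_model. Returns list(pred, conf) matrices
# (rows = variants, cols = tools).
vote_matrices <- function(data, tools, model, category) {
  pred <- matrix(NA_character_, nrow(data), length(tools),
                 dimnames = list(NULL, tools))
  conf <- matrix(NA_integer_, nrow(data), length(tools),
                 dimnames = list(NULL, tools))
  for (tl in tools) {
    cv <- get_curve(model, tl, category)
    tr <- transform_score(cv, data[[tl]])
    pred[, tl] <- tr$prediction
    conf[, tl] <- tr$confidence
  }
  list(pred = pred, conf = conf)
}

#' Re-calibrate the consensus score
#'
#' The weighted-vote consensus score is itself treated like a raw tool score
#' (polarity: higher is deleterious): a decision threshold is re-optimized on
#' the training labels and a binned confidence curve is fitted, exactly as for
#' the individual tools.
#'
#' @param scores Training consensus scores in \[-1, 1\].
#' @param labels Training labels.
#' @param n_bins,window Curve parameters.
#' @param category Optional category name stored on the curve.
#' @return List with `threshold`, `normalized_accuracy`, `curve`.
#' @export
calibrate_consensus <- function(scores, labels, n_bins = 66, window = 11,
                                category = NA_character_) {
  opt <- optimize_threshold(scores, labels, "higher_is_deleterious")
  curve <- fit_confidence_curve(scores, labels, opt$threshold,
                                "higher_is_deleterious",
                                n_bins = n_bins, window = window,
                                tool = "consensus", category = category)
  list(threshold = opt$threshold, normalized_accuracy = opt$normalized_accuracy,
       curve = curve)
}

#' Select the best tool subset for one category
#'
#' Enumerates every subset of two or more calibrated tools; for each subset it
#' computes the training consensus scores, re-optimizes the consensus
#' threshold, and keeps the subset with the highest training normalized
#' accuracy. Ties are broken toward fewer tools, then lexicographic tool
#' names. The best single tool is recorded for reporting but is only selected
#' when every multi-tool subset fails to calibrate. This mirrors the
#' observation that folding weak tools into the vote can reduce consensus
#' accuracy, so the subset is tuned per category.
#'
#' @param train Labeled training tibble for one category (columns `label` and
#'   one score column per tool).
#' @param model A fitted [fit_thresholds()] model covering this category.
#' @param category Category name.
#' @param specs Tool specs.
#' @param n_bins,window Curve parameters for the consensus curve.
#' @return An object of class `consensus_model`: list with `category`,
#'   `tools`, `threshold`, `curve`, `train_normalized_accuracy`,
#'   `best_single` (list: tool, normalized_accuracy), and `subset_scan`
#'   (tibble of all evaluated subsets).
#' @export
select_consensus_subset <- function(train, model, category, specs,
                                    n_bins = 66, window = 11) {
  tools <- sort(intersect(specs$tool, model$entries$tool[
    model$entries$category == category]))
  if (length(tools) < 2) abort("subset selection needs at least 2 calibrated tools")
  votes <- vote_matrices(train, tools, model, category)

  subsets <- unlist(lapply(2:length(tools), function(k) {
    utils::combn(tools, k, simplify = FALSE)
  }), recursive = FALSE)

  scan <- purrr::map(subsets, function(sub) {
    cs <- consensus_scores_matrix(votes$pred[, sub, drop = FALSE],
                                  votes$conf[, sub, drop = FALSE])
    keep <- !is.na(cs)
    opt <- tryCatch(
      optimize_threshold(cs[keep], train$label[keep], "higher_is_deleterious"),
      error = function(e) NULL
    )
    tibble(
      tools = paste(sub, collapse = "+"), size = length(sub),
      normalized_accuracy = if (is.null(opt)) NA_real_ else opt$normalized_accuracy
    )
  }) |> bind_rows()

  # best single tool, reported alongside (Table-2-style comparison)
  single <- purrr::map_dbl(tools, function(tl) {
    model$entries$train_normalized_accuracy[
      model$entries$tool == tl & model$entries$category == category]
  })
  best_single <- list(tool = tools[which.max(single)],
                      normalized_accuracy = max(single))

  ok <- which(!is.na(scan$normalized_accuracy))
  if (length(ok) == 0) {
    # degenerate: no multi-tool subset calibrates; fall back to best single tool
    sel_tools <- best_single$tool
    cs <- consensus_scores_matrix(votes$pred[, sel_tools, drop = FALSE],
                                  votes$conf[, sel_tools, drop = FALSE])
  } else {
    scan_ok <- scan[ok, ]
    best_na <- max(scan_ok$normalized_accuracy)
    cand <- scan_ok %>%
      filter(.data$normalized_accuracy == best_na) %>%
      arrange(.data$size, .data$tools)
    sel_tools <- strsplit(cand$tools[1], "+", fixed = TRUE)[[1]]
    cs <- consensus_scores_matrix(votes$pred[, sel_tools, drop = FALSE],
                                  votes$conf[, sel_tools, drop = FALSE])
  }
  keep <- !is.na(cs)
  calib <- calibrate_consensus(cs[keep], train$label[keep],
                               n_bins = n_bins, window = window,
                               category = category)
  structure(
    list(category = category, tools = sel_tools,
         threshold = calib$threshold, curve = calib$curve,
         train_normalized_accuracy = calib$normalized_accuracy,
         best_single = best_single, subset_scan = scan),
    class = "consensus_model"
  )
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model> category=%s tools={%s} train NA=%.3f (best single: %s %.3f)\n",
              x$category, paste(x$tools, collapse = ", "),
              x$train_normalized_accuracy,
              x$best_single$tool, x$best_single$normalized_accuracy))
  invisible(x)
}

#' Train the full consensus model bundle
#'
#' End-to-end trainer: per-tool, per-category thresholds and confidence
#' curves, then per-category consensus subset selection (or the full tool set
#' when `select_subsets = FALSE`) with consensus re-calibration.
#'
#' @param train Labeled training tibble (`label`, `category`, one score column
#'   per tool).
#' @param specs Tool specs.
#' @param n_bins,window Calibration parameters.
#' @param select_subsets Enumerate tool subsets per category (default `TRUE`);
#'   otherwise every category uses all tools.
#' @param seed Optional integer recorded in the bundle metadata.
#' @return An object of class `model_bundle`: list with `thresholds`
#'   (a `threshold_model`), `consensus` (named list of `consensus_model` per
#'   category), `specs`, and `metadata`.
#' @export
train_model <- function(train, specs, n_bins = 66, window = 11,
                        select_subsets = TRUE, seed = NULL) {
  validate_tool_specs(specs)
  thresholds <- fit_thresholds(train, specs, n_bins = n_bins, window = window)
  categories <- unique(train$category)
  consensus <- purrr::map(categories, function(cat) {
    sub <- train[train$category == cat, ]
    if (select_subsets && nrow(specs) >= 2) {
      select_consensus_subset(sub, thresholds, cat, specs,
                              n_bins = n_bins, window = window)
    } else {
      tools <- sort(specs$tool)
      votes <- vote_matrices(sub, tools, thresholds, cat)
      cs <- consensus_scores_matrix(votes$pred, votes$conf)
      keep <- !is.na(cs)
      calib <- calibrate_consensus(cs[keep], sub$label[keep],
                                   n_bins = n_bins, window = window,
                                   category = cat)
      structure(
        list(category = cat, tools = tools, threshold = calib$threshold,
             curve = calib$curve,
             train_normalized_accuracy = calib$normalized_accuracy,
             best_single = NULL, subset_scan = NULL),
        class = "consensus_model"
      )
    }
  })
  names(consensus) <- categories
  structure(
    list(thresholds = thresholds, consensus = consensus, specs = specs,
         metadata = list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                         n_bins = n_bins, window = window,
                         select_subsets = select_subsets,
                         seed = if (is.null(seed)) NA_integer_ else as.integer(seed))),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %d tools, %d categories\n",
              nrow(x$specs), length(x$consensus)))
  for (cm in x$consensus) print(cm)
  invisible(x)
}

#' Predict deleteriousness for variants
#'
#' Applies a trained bundle: for each variant the category is taken from the
#' `category` column (or computed with [classify_variants()] when gene models
#' are supplied); each selected tool's available raw score is transformed to a
#' vote; votes are combined by the confidence-weighted majority rule
#' (weights renormalized over the available tools); and the consensus score is
#' thresholded and mapped to a 0-99 confidence through the category's
#' consensus curve. Variants with no usable tool score are flagged
#' `NO_SCORES` and carry `NA` consensus fields.
#'
#' @param variants Variant tibble; needs a `category` column unless
#'   `gene_models` is given.
#' @param scores Score table (joined to variants by variant key).
#' @param bundle A [train_model()] bundle covering every category present.
#' @param gene_models Optional [read_gene_models()] result for on-the-fly
#'   categorization.
#' @return A tibble, one row per input variant in input order: the variant
#'   key columns, `category`, per-tool `<tool>_pred`/`<tool>_conf`,
#'   `consensus_score`, `consensus_prediction`, `consensus_confidence`, and
#'   logical `no_scores`.
#' @export
predict_variants <- function(variants, scores, bundle, gene_models = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  validate_variants(variants)
  if (!("category" %in% names(variants)) || anyNA(variants$category)) {
    if (is.null(gene_models)) {
      abort("variants lack categories; supply a `category` column or gene_models")
    }
    calls <- classify_variants(variants, gene_models)
    variants$category <- calls$category
  }
  missing_cat <- setdiff(unique(variants$category), names(bundle$consensus))
  if (length(missing_cat) > 0) {
    abort(sprintf("bundle has no consensus model for category: %s",
                  paste(missing_cat, collapse = ", ")))
  }

  specs <- bundle$specs
  joined <- variants %>%
    select(-dplyr::any_of(specs$tool)) %>%
    mutate(.key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    left_join(
      scores %>%
        mutate(.key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
        select(".key", dplyr::all_of(specs$tool)),
      by = ".key"
    )

  out <- joined %>%
    select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "id", "category")))
  for (tl in specs$tool) {
    out[[paste0(tl, "_pred")]] <- NA_character_
    out[[paste0(tl, "_conf")]] <- NA_integer_
  }
  out$consensus_score <- NA_real_
  out$consensus_prediction <- NA_character_
  out$consensus_confidence <- NA_integer_

  for (cat in unique(out$category)) {
    cm <- bundle$consensus[[cat]]
    rows <- which(out$category == cat)
    votes <- vote_matrices(joined[rows, , drop = FALSE], cm$tools,
                           bundle$thresholds, cat)
    for (tl in cm$tools) {
      out[[paste0(tl, "_pred")]][rows] <- votes$pred[, tl]
      out[[paste0(tl, "_conf")]][rows] <- votes$conf[, tl]
    }
    cs <- consensus_scores_matrix(votes$pred, votes$conf)
    tr <- transform_score(cm$curve, cs)
    out$consensus_score[rows] <- cs
    out$consensus_prediction[rows] <- tr$prediction
    out$consensus_confidence[rows] <- tr$confidence
  }
  out$no_scores <- is.na(out$consensus_score)
  out
}
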