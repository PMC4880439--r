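MODEL_SCHEMA_VERSION <- 1L

curve_to_list <- function(cv) {
  list(
    tool = cv$tool, category = cv$category,
    bin_edges = cv$bin_edges, bin_centers = cv$bin_centers,
    frac_deleterious = cv$frac_deleterious,
    smoothed_frac_deleterious = cv$smoothed_frac_deleterious,
    bin_n = cv$bin_n, threshold = cv$threshold, polarity = cv$polarity,
    n_bins = cv$n_bins, window = cv$window
  )
}

curve_from_list <- function(x) {
  structure(
    list(
      tool = x$tool %||% NA_character_, category = x$category %||% NA_character_,
      bin_edges = as.numeric(x$bin_edges), bin_centers = as.numeric(x$bin_centers),
      frac_deleterious = as.numeric(x$frac_deleterious),
      smoothed_frac_deleterious = as.numeric(x$smoothed_frac_deleterious),
      bin_n = as.integer(x$bin_n), threshold = as.numeric(x$threshold),
      polarity = x$polarity, n_bins = as.integer(x$n_bins),
      window = as.integer(x$window)
    ),
    class = "calibration_curve"
  )
}

#' Save a trained model bundle as JSON
#'
#' Writes one self-contained JSON document (with a `schema_version` field)
#' holding the tool specs, all thresholds, all calibration curves and the
#' per-category consensus models. Numeric fields are written at full
#' precision so that [load_model()] reproduces the bundle bit-exactly.
#'
#' @param bundle A [train_model()] bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    metadata = bundle$metadata,
    specs = bundle$specs,
    threshold_entries = bundle$thresholds$entries,
    threshold_params = list(n_bins = bundle$thresholds$n_bins,
                            window = bundle$thresholds$window),
    curves = unname(purrr::map(bundle$thresholds$curves, curve_to_list)),
    consensus = unname(purrr::map(bundle$consensus, function(cm) {
      list(
        category = cm$category, tools = cm$tools, threshold = cm$threshold,
        train_normalized_accuracy = cm$train_normalized_accuracy,
        best_single = cm$best_single,
        subset_scan = cm$subset_scan,
        curve = curve_to_list(cm$curve)
      )
    }))
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param path Path to the JSON file.
#' @return A `model_bundle`, equal to the saved one on all numeric fields.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("failed to parse model file %s: %s",
                                      path, conditionMessage(e)))
  )
  ver <- doc$schema_version
  if (is.null(ver) || !identical(as.integer(ver), MODEL_SCHEMA_VERSION)) {
    abort(sprintf("unsupported model schema version '%s' (this build reads version %d)",
                  as.character(ver %||% "missing"), MODEL_SCHEMA_VERSION))
  }
  # JSON null (a saved NA) comes back as a NULL list element; unlist() would
  # silently drop it, so map element-wise.
  chr <- function(x) vapply(x, function(e) if (is.null(e)) NA_character_ else as.character(e), character(1))
  num <- function(x) vapply(x, function(e) if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
  int <- function(x) vapply(x, function(e) if (is.null(e)) NA_integer_ else as.integer(e), integer(1))
  unbox <- function(x) lapply(x, unlist)
  specs <- tibble(tool = chr(doc$specs$tool), polarity = chr(doc$specs$polarity))
  te <- doc$threshold_entries
  entries <- tibble(
    tool = chr(te$tool), category = chr(te$category), polarity = chr(te$polarity),
    threshold = num(te$threshold),
    train_normalized_accuracy = num(te$train_normalized_accuracy),
    n_used = int(te$n_used)
  )
  curves <- list()
  for (x in doc$curves) {
    cv <- curve_from_list(unbox(x))
    curves[[curve_key(cv$tool, cv$category)]] <- cv
  }
  thresholds <- structure(
    list(entries = entries, curves = curves,
         n_bins = int(doc$threshold_params$n_bins),
         window = int(doc$threshold_params$window)),
    class = "threshold_model"
  )
  consensus <- list()
  for (x in doc$consensus) {
    cm <- structure(
      list(
        category = chr(x$category), tools = chr(x$tools),
        threshold = num(x$threshold),
        curve = curve_from_list(unbox(x$curve)),
        train_normalized_accuracy = num(x$train_normalized_accuracy),
        best_single = if (is.null(x$best_single)) NULL else
          list(tool = chr(x$best_single$tool),
               normalized_accuracy = num(x$best_single$normalized_accuracy)),
        subset_scan = if (is.null(x$subset_scan)) NULL else
          tibble(tools = chr(x$subset_scan$tools),
                 size = int(x$subset_scan$size),
                 normalized_accuracy = num(x$subset_scan$normalized_accuracy))
      ),
      class = "consensus_model"
    )
    consensus[[cm$category]] <- cm
  }
  meta <- doc$metadata
  meta$seed <- if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed)
  structure(
    list(thresholds = thresholds, consensus = consensus, specs = specs,
         metadata = meta),
    class = "model_bundle"
  )
}

#' Write predictions to TSV or VCF
#'
#' TSV output mirrors the prediction tibble. VCF output carries the
#' annotations in INFO fields declared in the header: `PS2_CAT` (category),
#' `PS2_PRED` (`D`/`N`), `PS2_CONF` (integer 0-99), per-tool
#' `<TOOL>_PRED`/`<TOOL>_CONF`, and a `NO_SCORES` flag for variants with no
#' usable tool score. Input order is preserved.
#'
#' @param preds A [predict_variants()] tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(preds)
    for (col in names(df)) {
      if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- "."
      if (is.double(df[[col]])) {
        # 17 significant digits so re-reading reproduces the doubles exactly
        df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.17g", df[[col]]))
      }
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    return(invisible(path))
  }
  tools <- unique(sub("_pred$", "", grep("_pred$", names(preds), value = TRUE)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=snvconsensus %s", as.character(utils::packageVersion("snvconsensus"))),
    "##INFO=<ID=PS2_CAT,Number=1,Type=String,Description=\"Variant category\">",
    "##INFO=<ID=PS2_PRED,Number=1,Type=Character,Description=\"Consensus prediction (D/N)\">",
    "##INFO=<ID=PS2_CONF,Number=1,Type=Integer,Description=\"Consensus confidence 0-99\">",
    "##INFO=<ID=NO_SCORES,Number=0,Type=Flag,Description=\"No tool scores available\">",
    unlist(lapply(tools, function(tl) c(
      sprintf("##INFO=<ID=%s_PRED,Number=1,Type=Character,Description=\"%s prediction (D/N)\">", toupper(tl), tl),
      sprintf("##INFO=<ID=%s_CONF,Number=1,Type=Integer,Description=\"%s confidence 0-99\">", toupper(tl), tl)
    ))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  info <- vapply(seq_len(nrow(preds)), function(i) {
    fields <- c(
      paste0("PS2_CAT=", dot(preds$category[i])),
      paste0("PS2_PRED=", dot(preds$consensus_prediction[i])),
      paste0("PS2_CONF=", dot(preds$consensus_confidence[i]))
    )
    for (tl in tools) {
      p <- preds[[paste0(tl, "_pred")]][i]
      cf <- preds[[paste0(tl, "_conf")]][i]
      if (!is.na(p)) {
        fields <- c(fields, paste0(toupper(tl), "_PRED=", p),
                    paste0(toupper(tl), "_CONF=", cf))
      }
    }
    if (isTRUE(preds$no_scores[i])) fields <- c(fields, "NO_SCORES")
    paste(fields, collapse = ";")
  }, character(1))
  id_col <- if ("id" %in% names(preds)) dot(preds$id) else rep(".", nrow(preds))
  body <- paste(preds$chrom, preds$pos, id_col, preds$ref, preds$alt,
                ".", ".", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Re-read a predictions TSV written by [write_predictions()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the same columns and types as the original
#'   prediction tibble (`"."` restored to `NA`).
#' @export
read_predictions_tsv <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = ".", check.names = FALSE)
  out <- as_tibble(raw)
  out$pos <- as.integer(out$pos)
  for (col in grep("_conf$|^consensus_confidence$", names(out), value = TRUE)) {
    out[[col]] <- as.integer(out[[col]])
  }
  if ("consensus_score" %in% names(out)) {
    out$consensus_score <- as.numeric(out$consensus_score)
  }
  if ("no_scores" %in% names(out)) out$no_scores <- as.logical(out$no_scores)
  out
}
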