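#' Declare an external prediction tool
#'
#' Each integrated tool contributes a raw score column; `polarity` records
#' whether larger or smaller raw scores indicate deleteriousness (CADD-like
#' tools are `"higher_is_deleterious"`, FitCons-like fitness scores would be
#' `"lower_is_deleterious"`).
#'
#' @param name Tool name (must match a score-table column).
#' @param polarity `"higher_is_deleterious"` or `"lower_is_deleterious"`.
#' @return A one-row tibble with columns `tool` and `polarity`.
#' @export
tool_spec <- function(name, polarity = c("higher_is_deleterious",
                                         "lower_is_deleterious")) {
  polarity <- match.arg(polarity)
  tibble(tool = as.character(name), polarity = polarity)
}

#' Combine tool specs
#'
#' @param ... One-row tibbles from [tool_spec()], or data frames of them.
#' @return A tibble with one row per tool; names must be unique.
#' @export
tool_specs <- function(...) {
  specs <- bind_rows(...)
  if (anyDuplicated(specs$tool)) {
    abort("tool names must be unique within a score table")
  }
  specs
}

validate_tool_specs <- function(specs) {
  if (!all(c("tool", "polarity") %in% names(specs))) {
    abort("tool specs need columns `tool` and `polarity`")
  }
  bad <- !specs$polarity %in% c("higher_is_deleterious", "lower_is_deleterious")
  if (any(bad)) abort("unknown polarity value in tool specs")
  if (anyDuplicated(specs$tool)) abort("duplicate tool names in tool specs")
  invisible(specs)
}

#' Read a per-variant raw-score table
#'
#' The table is a TSV with header `chrom`, `pos`, `ref`, `alt` followed by one
#' numeric column per declared tool; missing scores are encoded as `"."` (or
#' empty/`NA`). Duplicate variant keys are resolved last-wins with a warning.
#'
#' @param path Path to the TSV.
#' @param specs Tool specs from [tool_specs()]; every declared tool must have
#'   a column in the file.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt` and one numeric
#'   column per tool (`NA` = missing score). The tool specs are attached as
#'   attribute `tool_specs` (also retrievable with [get_tool_specs()]).
#' @export
read_score_table <- function(path, specs) {
  validate_tool_specs(specs)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, comment.char = "")
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(raw))) {
    abort(sprintf("score table %s must start with columns chrom, pos, ref, alt", path))
  }
  missing_tools <- setdiff(specs$tool, names(raw))
  if (length(missing_tools) > 0) {
    abort(sprintf("score table %s lacks column(s) for declared tool(s): %s",
                  path, paste(missing_tools, collapse = ", ")))
  }
  out <- tibble(
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    ref = raw$ref, alt = raw$alt
  )
  for (tl in specs$tool) {
    tok <- raw[[tl]]
    is_missing <- is.na(tok) | tok %in% c(".", "", "NA")
    val <- suppressWarnings(as.numeric(tok))
    bad <- !is_missing & is.na(val)
    if (any(bad)) {
      abort(sprintf("non-numeric score '%s' for tool %s at data line %d of %s",
                    tok[which(bad)[1]], tl, which(bad)[1], path))
    }
    val[is_missing] <- NA_real_
    out[[tl]] <- val
  }
  key <- variant_key(out)
  if (anyDuplicated(key)) {
    warn(sprintf("score table %s: %d duplicate variant key(s); keeping the last occurrence",
                 path, sum(duplicated(key))))
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  score_table(out, specs)
}

#' Attach tool specs to a score tibble
#'
#' @param scores Tibble with `chrom`, `pos`, `ref`, `alt` and one column per
#'   tool in `specs`.
#' @param specs Tool specs.
#' @return `scores` with the specs attached as attribute `tool_specs`.
#' @export
score_table <- function(scores, specs) {
  validate_tool_specs(specs)
  missing_tools <- setdiff(specs$tool, names(scores))
  if (length(missing_tools) > 0) {
    abort(sprintf("score tibble lacks tool column(s): %s",
                  paste(missing_tools, collapse = ", ")))
  }
  scores <- as_tibble(scores)
  attr(scores, "tool_specs") <- as_tibble(specs)
  scores
}

#' Retrieve the tool specs attached to a score table
#' @param scores A score table built by [read_score_table()] or [score_table()].
#' @return The tool-spec tibble.
#' @export
get_tool_specs <- function(scores) {
  specs <- attr(scores, "tool_specs", exact = TRUE)
  if (is.null(specs)) abort("score table carries no tool specs; build it with score_table()")
  specs
}

#' Write a score table to TSV (missing scores as ".")
#' @param scores Score table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  specs <- get_tool_specs(scores)
  df <- as.data.frame(scores[, c("chrom", "pos", "ref", "alt", specs$tool)])
  for (tl in specs$tool) {
    df[[tl]] <- ifelse(is.na(df[[tl]]), ".", format(df[[tl]], digits = 15, trim = TRUE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
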