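#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

BASES <- c("A", "C", "G", "T")
CATEGORIES <- c("regulatory", "splicing", "missense", "synonymous", "nonsense")
LABELS <- c("deleterious", "neutral")

#' Normalize a chromosome name
#'
#' Chromosome names are compared after stripping a leading `"chr"` prefix so
#' that UCSC-style (`chr1`) and Ensembl-style (`1`) inputs interoperate.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with any leading `"chr"` removed.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Variant key
#'
#' The canonical `chrom:pos:ref:alt` key (chromosome normalized) used to join
#' variants with score tables and to detect overlaps between datasets.
#'
#' @param chrom,pos,ref,alt Vectors of equal length, or a data frame with
#'   those columns passed as `chrom`.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(variant_key(df$chrom, df$pos, df$ref, df$alt))
  }
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

new_variant_tbl <- function(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            id = NA_character_, label = NA_character_,
                            date = as.Date(NA), category = NA_character_) {
  tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    id = as.character(id), label = as.character(label),
    date = as.Date(date), category = as.character(category)
  )
}

validate_variants <- function(variants, context = "variants") {
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", context,
                  paste(missing, collapse = ", ")))
  }
  if (any(variants$pos < 1, na.rm = TRUE)) {
    abort(sprintf("%s contains positions < 1 (coordinates are 1-based)", context))
  }
  bad <- !(variants$ref %in% BASES) | !(variants$alt %in% BASES) |
    variants$ref == variants$alt
  if (any(bad)) {
    abort(sprintf("%s contains %d non-SNV or degenerate record(s): ref/alt must be single bases A/C/G/T with ref != alt",
                  context, sum(bad)))
  }
  invisible(variants)
}

is_snv_allele <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES & ref != alt
}

#' Read variants from VCF or TSV
#'
#' Reads biallelic SNVs into a variant tibble. Multi-allelic VCF records are
#' split into one row per alternate allele; alleles that are not simple
#' nucleotide substitutions (indels, MNVs, symbolic alleles) are skipped and
#' the skip count is reported via a message.
#'
#' The TSV dialect has at least four columns `chrom`, `pos`, `ref`, `alt`
#' (1-based positions), with optional `id`, `label`, `date` and `category`
#' columns; a header row is required.
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"tsv"`. VCF 4.x is parsed with \pkg{vcfR}.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `id`, `label`,
#'   `date`, `category` (one row per SNV allele). The number of skipped
#'   non-SNV alleles is attached as attribute `n_skipped`.
#' @export
read_variants <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- switch(format,
    vcf = read_variants_vcf(path),
    tsv = read_variants_tsv(path)
  )
  if (nrow(out) == 0) {
    abort(sprintf("no biallelic SNVs retained from %s", path))
  }
  out
}

read_variants_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("failed to parse VCF %s: %s",
                                      path, conditionMessage(e)))
  )
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) {
    # a single-record VCF yields a bare named vector; restore the matrix shape
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(new_variant_tbl())
  rows <- as_tibble(fix) |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::separate_rows("ALT", sep = ",") |>
    mutate(
      pos = suppressWarnings(as.integer(.data$POS)),
      snv = is_snv_allele(.data$REF, .data$ALT)
    )
  n_skipped <- sum(!rows$snv)
  if (n_skipped > 0) {
    inform(sprintf("read_variants: skipped %d non-SNV allele(s) in %s",
                   n_skipped, path))
  }
  kept <- filter(rows, .data$snv)
  out <- new_variant_tbl(
    chrom = kept$CHROM, pos = kept$pos, ref = kept$REF, alt = kept$ALT,
    id = ifelse(is.na(kept$ID) | kept$ID == ".", NA_character_, kept$ID)
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

read_variants_tsv <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character",
                      check.names = FALSE, comment.char = ""),
    error = function(e) abort(sprintf("failed to parse TSV %s: %s",
                                      path, conditionMessage(e)))
  )
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(raw))) {
    abort(sprintf("TSV %s must have header columns chrom, pos, ref, alt", path))
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  if (anyNA(pos) && nrow(raw) > 0) {
    bad <- which(is.na(pos))[1]
    abort(sprintf("non-integer position at data line %d of %s", bad, path))
  }
  snv <- is_snv_allele(raw$ref, raw$alt)
  n_skipped <- sum(!snv)
  if (n_skipped > 0) {
    inform(sprintf("read_variants: skipped %d non-SNV record(s) in %s",
                   n_skipped, path))
  }
  keep <- raw[snv, , drop = FALSE]
  grab <- function(col, default) {
    if (col %in% names(keep)) keep[[col]] else rep(default, nrow(keep))
  }
  out <- new_variant_tbl(
    chrom = keep$chrom, pos = pos[snv], ref = keep$ref, alt = keep$alt,
    id = grab("id", NA_character_),
    label = grab("label", NA_character_),
    date = as.Date(grab("date", NA_character_)),
    category = grab("category", NA_character_)
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write variants to TSV
#'
#' Inverse of [read_variants()] for the TSV dialect; optional all-`NA`
#' columns are dropped.
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  validate_variants(variants)
  df <- as.data.frame(variants)
  for (col in c("id", "label", "date", "category")) {
    if (col %in% names(df) && all(is.na(df[[col]]))) df[[col]] <- NULL
  }
  if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
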