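CATEGORY_SEVERITY <- c(nonsense = 5, missense = 4, splicing = 3,
                       synonymous = 2, regulatory = 1)

# 1-based position of a genomic coordinate within the spliced CDS (in
# translation orientation), or NA when the position is not coding.
cds_offset <- function(pos, cds, strand) {
  hit <- which(cds$start <= pos & pos <= cds$end)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(cds$end[seq_len(hit - 1)] - cds$start[seq_len(hit - 1)] + 1) else 0L
  off_plus <- before + (pos - cds$start[hit] + 1L)
  total <- sum(cds$end - cds$start + 1)
  if (strand == "-") total - off_plus + 1L else off_plus
}

# Coding consequence of a single-base substitution by local codon
# translation. `tx` is a plain list (one transcript) as built by
# classify_variants. Returns list(category, detail).
coding_call <- function(tx, pos, ref, alt) {
  cds <- tx$cds
  cpos <- cds_offset(pos, cds, tx$strand)
  ref_t <- if (tx$strand == "-") comp_base[[ref]] else ref
  alt_t <- if (tx$strand == "-") comp_base[[alt]] else alt
  seq_ref <- substr(tx$cds_seq, cpos, cpos)
  if (seq_ref != ref_t) {
    abort(sprintf("reference allele mismatch within CDS of %s at %s:%d (CDS has %s, variant ref %s)",
                  tx$transcript_id, tx$chrom, pos, seq_ref, ref_t))
  }
  codon_idx <- (cpos - 1L) %/% 3L + 1L
  within <- (cpos - 1L) %% 3L + 1L
  cstart <- (codon_idx - 1L) * 3L + 1L
  ref_codon <- substr(tx$cds_seq, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_t
  ref_aa <- GENCODE[[ref_codon]]
  alt_aa <- GENCODE[[alt_codon]]
  category <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
              else if (alt_aa != ref_aa) "missense"
              else "synonymous"
  list(category = category,
       detail = sprintf("%s%d%s (%s>%s)", ref_aa, codon_idx, alt_aa,
                        ref_codon, alt_codon))
}

# Distance from an intronic position to the nearest exon boundary of one
# transcript; Inf when the position is not inside the transcript span.
intron_boundary_distance <- function(pos, exons) {
  span_lo <- min(exons$start)
  span_hi <- max(exons$end)
  if (pos < span_lo || pos > span_hi) return(Inf)
  in_exon <- any(exons$start <= pos & pos <= exons$end)
  if (in_exon) return(Inf)
  min(c(abs(pos - exons$end[exons$end < pos]),
        abs(exons$start[exons$start > pos] - pos)))
}

# Category call for one variant against one transcript.
transcript_call <- function(tx, pos, ref, alt, splice_window) {
  cds <- tx$cds
  exons <- tx$exons
  if (nrow(cds) > 0 && any(cds$start <= pos & pos <= cds$end)) {
    return(coding_call(tx, pos, ref, alt))
  }
  if (any(exons$start <= pos & pos <= exons$end)) {
    return(list(category = "regulatory", detail = "non-coding exonic (UTR/ncRNA)"))
  }
  d <- intron_boundary_distance(pos, exons)
  if (is.finite(d) && d <= splice_window) {
    return(list(category = "splicing", detail = sprintf("intron, %d bp from exon boundary", d)))
  }
  if (is.finite(d)) {
    return(list(category = "regulatory", detail = "deep intronic"))
  }
  list(category = "regulatory", detail = "intergenic/flanking")
}

#' Assign each SNV one of five genomic categories
#'
#' Classifies variants as regulatory, splicing, missense, synonymous or
#' nonsense from transcript models and the reference sequence. Within a CDS
#' the affected codon is translated for the reference and alternate alleles
#' (on the reverse complement for minus-strand transcripts): a gained stop is
#' nonsense, an amino-acid change (including start or stop loss) is missense,
#' an unchanged residue is synonymous. Intronic positions within
#' `splice_window` bp of any exon boundary are splicing. Everything else —
#' intergenic, deep intronic, UTR, non-coding genes, flanking regions —
#' collapses into regulatory, the non-exonic, non-splicing remainder of the
#' five-way scheme. When transcripts disagree, the most severe call wins:
#' nonsense > missense > splicing > synonymous > regulatory.
#'
#' The variant's ref allele is checked against the reference sequence; a
#' mismatch is a data-integrity error naming the position.
#'
#' @param variants Variant tibble (SNVs).
#' @param models A [read_gene_models()] object.
#' @param splice_window Intronic bases next to each exon boundary called
#'   splicing (default 2, the canonical splice-site dinucleotide).
#' @return A tibble with one row per variant: the key columns plus
#'   `category`, `detail` and `transcript_id` (`NA` for intergenic calls).
#' @export
classify_variants <- function(variants, models, splice_window = 2) {
  stopifnot(inherits(models, "gene_models"))
  validate_variants(variants)
  tx_tbl <- models$transcripts
  genome <- models$genome
  n <- nrow(variants)
  category <- character(n)
  detail <- character(n)
  tx_id <- rep(NA_character_, n)
  chrom_n <- norm_chrom(variants$chrom)

  # plain-list transcript records: tibble row subsetting inside the variant
  # loop dominates runtime otherwise
  tx_list <- lapply(seq_len(nrow(tx_tbl)), function(j) {
    list(transcript_id = tx_tbl$transcript_id[j], chrom = tx_tbl$chrom[j],
         strand = tx_tbl$strand[j], exons = tx_tbl$exons[[j]],
         cds = tx_tbl$cds[[j]], cds_seq = tx_tbl$cds_seq[j])
  })
  idx_by_chrom <- split(seq_along(tx_list), tx_tbl$chrom)

  for (i in seq_len(n)) {
    chrom <- chrom_n[i]
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    if (chrom %in% names(genome)) {
      genome_ref <- substr(genome[[chrom]], pos, pos)
      if (!identical(genome_ref, ref)) {
        abort(sprintf("reference allele mismatch at %s:%d: reference has '%s', variant ref is '%s'",
                      chrom, pos, genome_ref, ref))
      }
    }
    idx <- idx_by_chrom[[chrom]]
    best <- list(category = "regulatory", detail = "intergenic/flanking")
    best_tx <- NA_character_
    for (j in idx) {
      tx <- tx_list[[j]]
      call <- transcript_call(tx, pos, ref, alt, splice_window)
      if (CATEGORY_SEVERITY[[call$category]] > CATEGORY_SEVERITY[[best$category]] ||
          (is.na(best_tx) && call$category == best$category &&
             call$detail != "intergenic/flanking")) {
        best <- call
        best_tx <- tx$transcript_id
      }
    }
    category[i] <- best$category
    detail[i] <- best$detail
    tx_id[i] <- best_tx
  }
  tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    category = category, detail = detail, transcript_id = tx_id
  )
}
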