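#' Read transcript models from GFF3/GTF plus a reference FASTA
#'
#' Parses gene annotations with \pkg{rtracklayer} and the reference with
#' \pkg{Biostrings} into one transcript model per mRNA/transcript feature.
#' Exon and CDS intervals are 1-based closed, sorted by genomic position.
#' Transcripts whose total CDS length is not divisible by 3 are dropped with
#' a warning; a CDS on a chromosome absent from the FASTA is an error.
#'
#' @param path GFF3 or GTF file.
#' @param fasta Reference FASTA covering all referenced chromosomes.
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return An object of class `gene_models`: list with `transcripts` (tibble
#'   with columns `transcript_id`, `chrom`, `strand`, `exons` and `cds`
#'   list-columns of start/end tibbles, `cds_seq` spliced coding sequence in
#'   translation orientation) and `genome` (named character vector of
#'   chromosome sequences, names normalized with [norm_chrom()]).
#' @export
read_gene_models <- function(path, fasta, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  genome <- load_genome(fasta)

  feat <- tibble(
    chrom = norm_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type)
  )
  if (format == "gtf") {
    feat$tx <- as.character(gr$transcript_id)
  } else {
    parent <- gr$Parent
    feat$tx <- vapply(seq_along(gr), function(i) {
      p <- parent[[i]]
      if (length(p) == 0) NA_character_ else sub("^transcript:", "", p[1])
    }, character(1))
  }
  feat <- filter(feat, .data$type %in% c("exon", "CDS"), !is.na(.data$tx))
  if (nrow(feat) == 0) abort(sprintf("no exon/CDS features found in %s", path))

  tx_ids <- unique(feat$tx)
  rows <- purrr::map(tx_ids, function(id) {
    f <- feat[feat$tx == id, ]
    exons <- f %>% filter(.data$type == "exon") %>%
      arrange(.data$start) %>% select("start", "end")
    cds <- f %>% filter(.data$type == "CDS") %>%
      arrange(.data$start) %>% select("start", "end")
    if (nrow(exons) == 0) exons <- cds  # CDS-only annotations
    chrom <- f$chrom[1]
    strand <- f$strand[1]
    if (nrow(cds) > 0 && !(chrom %in% names(genome))) {
      abort(sprintf("CDS of transcript %s references chromosome %s absent from FASTA",
                    id, chrom))
    }
    cds_len <- if (nrow(cds) > 0) sum(cds$end - cds$start + 1) else 0L
    if (cds_len %% 3 != 0) {
      warn(sprintf("dropping transcript %s: CDS length %d not divisible by 3",
                   id, cds_len))
      return(NULL)
    }
    cds_seq <- if (nrow(cds) > 0) spliced_seq(genome[[chrom]], cds, strand) else ""
    tibble(transcript_id = id, chrom = chrom, strand = strand,
           exons = list(exons), cds = list(cds), cds_seq = cds_seq)
  })
  transcripts <- bind_rows(rows)
  structure(list(transcripts = transcripts, genome = genome),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d transcript(s) on %d sequence(s)\n",
              nrow(x$transcripts), length(x$genome)))
  invisible(x)
}

load_genome <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  out <- as.character(seqs)
  names(out) <- norm_chrom(sub("\\s.*$", "", names(seqs)))
  out
}

# Spliced sequence of sorted plus-strand intervals, reverse-complemented for
# minus-strand transcripts so the result reads in translation orientation.
spliced_seq <- function(chrom_seq, intervals, strand) {
  parts <- substring(chrom_seq, intervals$start, intervals$end)
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

GENCODE <- as.character(Biostrings::GENETIC_CODE)
names(GENCODE) <- names(Biostrings::GENETIC_CODE)

translate_cds <- function(cds_seq) {
  n <- nchar(cds_seq)
  codons <- substring(cds_seq, seq(1, n, 3), seq(3, n, 3))
  paste(GENCODE[codons], collapse = "")
}
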