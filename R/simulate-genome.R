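STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  pool <- setdiff(names(GENCODE), STOP_CODONS)
  sample(pool, n, replace = TRUE)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate a miniature annotated genome with planted variants
#'
#' Builds one small chromosome carrying `n_genes` protein-coding genes
#' (random CDS starting with ATG and ending in a stop codon, length divisible
#' by 3, one to three exons with introns of at least 20 bp, both strands
#' represented) separated by intergenic spacers, and plants at least three
#' SNVs of each of the five categories with algorithmically guaranteed truth:
#' coding variants are labeled by whole-CDS retranslation of the mutant
#' sequence, splicing variants sit 1-2 bp inside an intron next to an exon
#' boundary, and regulatory variants sit in intergenic space or deep inside
#' introns. Planted variants alternate deleterious/neutral labels and carry
#' synthetic submission dates spanning the date-split cutoff. The whole
#' fixture is a pure function of the seed.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (>= 2 recommended so both strands appear).
#' @param intergenic_length Spacer length between genes (and at both ends).
#' @return An object of class `genome_fixture`: list with `genome` (named
#'   character), `features` (GFF-style tibble), `variants` (truth tibble
#'   with `chrom`, `pos`, `ref`, `alt`, `id`, `label`, `date`, `category`),
#'   and `models` (the corresponding `gene_models` object).
#' @export
simulate_genome <- function(seed = 1, n_genes = 6, intergenic_length = 300) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (intergenic_length < 100) abort("intergenic_length must be >= 100")
  set.seed(as.integer(seed))
  chrom <- "1"
  seq_parts <- character(0)
  cursor <- 0L
  features <- list()
  spacer0 <- random_dna(intergenic_length)
  seq_parts <- c(seq_parts, spacer0)
  cursor <- cursor + nchar(spacer0)

  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2 == 1) "+" else "-"
    n_codons <- sample(22:60, 1)
    cds_sense <- paste0("ATG", paste(random_codons(n_codons - 2), collapse = ""),
                        sample(STOP_CODONS, 1))
    cds_len <- nchar(cds_sense)
    # first two genes always multi-exon so splice sites and deep introns exist
    n_exons <- if (g <= 2) 3L else sample(1:3, 1)
    # cut the CDS into n_exons pieces, each at least 6 bp
    if (n_exons > 1) {
      cuts <- sort(sample(seq(6, cds_len - 6, by = 3), n_exons - 1))
    } else cuts <- integer(0)
    piece_bounds <- cbind(c(1, cuts + 1), c(cuts, cds_len))
    introns <- replicate(max(0, n_exons - 1),
                         paste0("GT", random_dna(sample(21:36, 1)), "AG"))
    # assemble the gene block in sense orientation; record exon offsets
    block <- ""
    exon_off <- matrix(0L, n_exons, 2)
    for (e in seq_len(n_exons)) {
      exon_seq <- substr(cds_sense, piece_bounds[e, 1], piece_bounds[e, 2])
      exon_off[e, 1] <- nchar(block) + 1L
      block <- paste0(block, exon_seq)
      exon_off[e, 2] <- nchar(block)
      if (e < n_exons) block <- paste0(block, introns[e])
    }
    b_len <- nchar(block)
    if (strand == "-") {
      block <- revcomp(block)
      exon_off <- cbind(b_len - exon_off[, 2] + 1L, b_len - exon_off[, 1] + 1L)
      exon_off <- exon_off[order(exon_off[, 1]), , drop = FALSE]
    }
    gene_start <- cursor + 1L
    seq_parts <- c(seq_parts, block)
    cursor <- cursor + b_len
    tx <- sprintf("tx%d", g)
    features[[g]] <- tibble(
      chrom = chrom, transcript_id = tx, gene_id = sprintf("gene%d", g),
      strand = strand,
      exon_start = gene_start + exon_off[, 1] - 1L,
      exon_end = gene_start + exon_off[, 2] - 1L
    )
    spacer <- random_dna(intergenic_length)
    seq_parts <- c(seq_parts, spacer)
    cursor <- cursor + nchar(spacer)
  }
  genome <- stats::setNames(paste(seq_parts, collapse = ""), chrom)
  feat <- bind_rows(features)
  models <- models_from_features(feat, genome)
  variants <- plant_variants(models, feat, intergenic_length)
  structure(list(genome = genome, features = feat, variants = variants,
                 models = models, seed = as.integer(seed)),
            class = "genome_fixture")
}

# Build a gene_models object directly from the fixture's feature tibble
# (exons double as CDS: the synthetic genes are CDS-only).
models_from_features <- function(feat, genome) {
  rows <- feat %>%
    group_by(.data$transcript_id) %>%
    group_map(function(f, key) {
      iv <- tibble(start = f$exon_start, end = f$exon_end) %>% arrange(.data$start)
      tibble(transcript_id = key$transcript_id[1], chrom = f$chrom[1],
             strand = f$strand[1], exons = list(iv), cds = list(iv),
             cds_seq = spliced_seq(genome[[f$chrom[1]]], iv, f$strand[1]))
    }) %>% bind_rows()
  structure(list(transcripts = rows, genome = genome), class = "gene_models")
}

#' Protein translation of a transcript with one substituted base
#'
#' Whole-CDS retranslation: substitutes `alt` at genomic position `pos`,
#' re-extracts the spliced CDS and translates it in full. Used by the genome
#' simulator to guarantee the truth of planted coding variants.
#'
#' @param models A `gene_models` object.
#' @param transcript_id Transcript to translate.
#' @param pos Genomic position (1-based); `NULL` for the unmutated protein.
#' @param alt Alternate base.
#' @return The amino-acid string (stop codons as `*`).
#' @export
mutant_protein <- function(models, transcript_id, pos = NULL, alt = NULL) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) != 1) abort(sprintf("unknown transcript %s", transcript_id))
  chrom_seq <- models$genome[[tx$chrom]]
  if (!is.null(pos)) substr(chrom_seq, pos, pos) <- alt
  translate_cds(spliced_seq(chrom_seq, tx$cds[[1]], tx$strand))
}

# Coding category by whole-protein comparison (the construction guarantee).
retranslation_category <- function(models, transcript_id, pos, alt) {
  p_ref <- mutant_protein(models, transcript_id)
  p_alt <- mutant_protein(models, transcript_id, pos, alt)
  if (p_alt == p_ref) return("synonymous")
  diff_at <- which(strsplit(p_alt, "")[[1]] != strsplit(p_ref, "")[[1]])
  aa_alt <- strsplit(p_alt, "")[[1]][diff_at[1]]
  aa_ref <- strsplit(p_ref, "")[[1]][diff_at[1]]
  if (aa_alt == "*" && aa_ref != "*") "nonsense" else "missense"
}

plant_variants <- function(models, feat, intergenic_length, per_category = 3L) {
  genome <- models$genome
  chrom <- names(genome)[1]
  chrom_seq <- genome[[chrom]]
  base_at <- function(p) substr(chrom_seq, p, p)
  picked <- list()

  # coding: walk CDS positions in transcript order, classify every alt by
  # retranslation, keep the first hits per class
  want <- c(missense = per_category, synonymous = per_category,
            nonsense = per_category)
  got <- c(missense = 0L, synonymous = 0L, nonsense = 0L)
  for (ti in seq_len(nrow(models$transcripts))) {
    tx <- models$transcripts[ti, ]
    cds <- tx$cds[[1]]
    positions <- unlist(purrr::map2(cds$start, cds$end, seq))
    for (p in positions) {
      if (all(got >= want)) break
      ref <- base_at(p)
      for (alt in setdiff(BASES, ref)) {
        cat <- retranslation_category(models, tx$transcript_id, p, alt)
        if (got[[cat]] < want[[cat]]) {
          got[[cat]] <- got[[cat]] + 1L
          picked[[length(picked) + 1]] <- tibble(
            chrom = chrom, pos = p, ref = ref, alt = alt, category = cat)
          break
        }
      }
    }
  }

  # splicing: intronic bases 1-2 bp past exon boundaries
  spl <- list()
  for (ti in seq_len(nrow(models$transcripts))) {
    exons <- models$transcripts$exons[[ti]]
    if (nrow(exons) < 2) next
    for (e in seq_len(nrow(exons) - 1)) {
      spl[[length(spl) + 1]] <- exons$end[e] + 1L       # donor side
      spl[[length(spl) + 1]] <- exons$start[e + 1] - 2L # acceptor side
    }
  }
  spl <- utils::head(unique(unlist(spl)), max(per_category, 4L))
  for (p in spl) {
    ref <- base_at(p)
    picked[[length(picked) + 1]] <- tibble(
      chrom = chrom, pos = p, ref = ref,
      alt = setdiff(BASES, ref)[1], category = "splicing")
  }

  # regulatory: intergenic space and (when available) deep intronic bases
  gene_lo <- min(feat$exon_start)
  reg_pos <- c(
    seq(50L, gene_lo - 10L, length.out = per_category) |> round() |> as.integer()
  )
  deep <- NULL
  for (ti in seq_len(nrow(models$transcripts))) {
    exons <- models$transcripts$exons[[ti]]
    if (nrow(exons) < 2) next
    mid <- (exons$end[1] + exons$start[2]) %/% 2L
    if (mid - exons$end[1] > 5L && exons$start[2] - mid > 5L) deep <- c(deep, mid)
  }
  reg_pos <- c(reg_pos, utils::head(deep, 2L))
  for (p in reg_pos) {
    ref <- base_at(p)
    picked[[length(picked) + 1]] <- tibble(
      chrom = chrom, pos = as.integer(p), ref = ref,
      alt = setdiff(BASES, ref)[1], category = "regulatory")
  }

  out <- bind_rows(picked) %>% distinct(.data$chrom, .data$pos, .data$alt,
                                        .keep_all = TRUE)
  n <- nrow(out)
  out %>% mutate(
    id = sprintf("planted_%03d", seq_len(n)),
    label = ifelse(seq_len(n) %% 2 == 1, "deleterious", "neutral"),
    date = as.Date("2013-06-01") + (seq_len(n) * 97L) %% 1400L
  ) %>% select("chrom", "pos", "ref", "alt", "id", "label", "date", "category")
}

#' Write a genome fixture to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `genes.gtf` and `variants.tsv` into a
#' directory. Output is byte-identical across runs for the same fixture.
#'
#' @param fixture A [simulate_genome()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "genome_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # FASTA, 70-column wrapped
  fa <- file.path(dir, "genome.fa")
  lines <- character(0)
  for (nm in names(fixture$genome)) {
    s <- fixture$genome[[nm]]
    starts <- seq(1, nchar(s), by = 70)
    lines <- c(lines, paste0(">", nm), substring(s, starts, pmin(starts + 69, nchar(s))))
  }
  writeLines(lines, fa)
  write_gff3(fixture$features, fixture$models, file.path(dir, "genes.gff3"))
  write_gtf(fixture$features, file.path(dir, "genes.gtf"))
  write_variants_tsv(fixture$variants, file.path(dir, "variants.tsv"))
  invisible(dir)
}

cds_phases <- function(iv, strand) {
  lens <- iv$end - iv$start + 1L
  order_tx <- if (strand == "-") rev(seq_len(nrow(iv))) else seq_len(nrow(iv))
  phase <- integer(nrow(iv))
  consumed <- 0L
  for (e in order_tx) {
    phase[e] <- (3L - consumed %% 3L) %% 3L
    consumed <- consumed + lens[e]
  }
  phase
}

write_gff3 <- function(feat, models, path) {
  lines <- "##gff-version 3"
  for (tx in unique(feat$transcript_id)) {
    f <- feat[feat$transcript_id == tx, ]
    iv <- tibble(start = f$exon_start, end = f$exon_end) %>% arrange(.data$start)
    phase <- cds_phases(iv, f$strand[1])
    lines <- c(lines,
      sprintf("%s\tsnvconsensus\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              f$chrom[1], min(iv$start), max(iv$end), f$strand[1], f$gene_id[1]),
      sprintf("%s\tsnvconsensus\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              f$chrom[1], min(iv$start), max(iv$end), f$strand[1], tx, f$gene_id[1]),
      sprintf("%s\tsnvconsensus\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              f$chrom[1], iv$start, iv$end, f$strand[1], tx, seq_len(nrow(iv)), tx),
      sprintf("%s\tsnvconsensus\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
              f$chrom[1], iv$start, iv$end, f$strand[1], phase, tx, tx)
    )
  }
  writeLines(lines, path)
}

write_gtf <- function(feat, path) {
  lines <- character(0)
  for (tx in unique(feat$transcript_id)) {
    f <- feat[feat$transcript_id == tx, ]
    iv <- tibble(start = f$exon_start, end = f$exon_end) %>% arrange(.data$start)
    phase <- cds_phases(iv, f$strand[1])
    attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", f$gene_id[1], tx)
    lines <- c(lines,
      sprintf("%s\tsnvconsensus\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              f$chrom[1], min(iv$start), max(iv$end), f$strand[1], attrs),
      sprintf("%s\tsnvconsensus\texon\t%d\t%d\t.\t%s\t.\t%s",
              f$chrom[1], iv$start, iv$end, f$strand[1], attrs),
      sprintf("%s\tsnvconsensus\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
              f$chrom[1], iv$start, iv$end, f$strand[1], phase, attrs)
    )
  }
  writeLines(lines, path)
}
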