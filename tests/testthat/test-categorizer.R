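# A tiny hand-built gene on the plus strand:
# chrom "1", 1-120; CDS = [31,48] + [70,87] (two exons, intron 49-69),
# coding sequence ATG AAA CAA TTT GGA TC | A CTG CAT CAA GCG TAA
hand_genome <- function() {
  pre <- strrep("T", 30)
  exon1 <- "ATGAAACAATTTGGATCA"  # 18 bp
  intron <- paste0("GT", strrep("C", 17), "AG")  # 21 bp, 49-69
  exon2 <- "CTGCATCAAGCGAAATAA"  # 18 bp, ends at the stop codon
  post <- strrep("A", 12)
  seq <- paste0(pre, exon1, intron, exon2, post)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">1", seq), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t31\t87\t.\t+\t.\tID=g1",
    "1\ttest\tmRNA\t31\t87\t.\t+\t.\tID=t1;Parent=g1",
    "1\ttest\texon\t31\t48\t.\t+\t.\tParent=t1",
    "1\ttest\texon\t70\t87\t.\t+\t.\tParent=t1",
    "1\ttest\tCDS\t31\t48\t.\t+\t0\tParent=t1",
    "1\ttest\tCDS\t70\t87\t.\t+\t0\tParent=t1"
  ), gff)
  list(fa = fa, gff = gff, seq = seq)
}

test_that("codon-level calls follow the standard genetic code", {
  hg <- hand_genome()
  gm <- read_gene_models(hg$gff, hg$fa)
  expect_equal(nrow(gm$transcripts), 1)
  expect_equal(substr(gm$transcripts$cds_seq, 1, 6), "ATGAAA")

  # codon 2 AAA: third base A->G gives AAG, Lys->Lys: synonymous
  syn <- classify_variants(mk_variants("1", 36L, ref = "A", alt = "G"), gm)
  expect_equal(syn$category, "synonymous")
  expect_match(syn$detail, "K2K")

  # codon 3 CAA: first base C->T gives TAA, Gln->stop: nonsense
  non <- classify_variants(mk_variants("1", 37L, ref = "C", alt = "T"), gm)
  expect_equal(non$category, "nonsense")

  # codon 2 AAA: first base A->C gives CAA, Lys->Gln: missense
  mis <- classify_variants(mk_variants("1", 34L, ref = "A", alt = "C"), gm)
  expect_equal(mis$category, "missense")
})

test_that("splice-window and regulatory fallbacks apply", {
  hg <- hand_genome()
  gm <- read_gene_models(hg$gff, hg$fa)
  # intron starts at 49; positions 49,50 are 1-2 bp from the exon boundary
  s1 <- classify_variants(mk_variants("1", 50L, ref = "T", alt = "A"), gm)
  expect_equal(s1$category, "splicing")
  s2 <- classify_variants(mk_variants("1", 68L, ref = "A", alt = "T"), gm)
  expect_equal(s2$category, "splicing")  # 2 bp before exon2
  # deep intron (position 58, 10 bp past the exon) is regulatory
  deep <- classify_variants(mk_variants("1", 58L, ref = "C", alt = "T"), gm)
  expect_equal(deep$category, "regulatory")
  # but widens with the configurable window
  deep_w <- classify_variants(mk_variants("1", 58L, ref = "C", alt = "T"), gm,
                              splice_window = 10)
  expect_equal(deep_w$category, "splicing")
  # far upstream is regulatory
  up <- classify_variants(mk_variants("1", 5L, ref = "T", alt = "C"), gm)
  expect_equal(up$category, "regulatory")
})

test_that("a reference-allele mismatch is a data-integrity error naming the position", {
  hg <- hand_genome()
  gm <- read_gene_models(hg$gff, hg$fa)
  expect_error(classify_variants(mk_variants("1", 31L, ref = "C", alt = "G"), gm),
               "31")
})

test_that("transcripts with CDS length not divisible by 3 are dropped with a warning", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">1", strrep("ACGT", 50)), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tmRNA\t11\t110\t.\t+\t.\tID=bad",
    "1\ttest\texon\t11\t110\t.\t+\t.\tParent=bad",
    "1\ttest\tCDS\t11\t110\t.\t+\t0\tParent=bad"
  ), gff)
  expect_warning(gm <- read_gene_models(gff, fa), "not divisible by 3")
  expect_equal(nrow(gm$transcripts), 0)
})

test_that("GTF and GFF3 encodings of the simulated genes give identical models", {
  fx <- simulate_genome(seed = 11, n_genes = 4)
  dir <- tempfile()
  write_genome_fixture(fx, dir)
  g1 <- read_gene_models(file.path(dir, "genes.gff3"), file.path(dir, "genome.fa"))
  g2 <- read_gene_models(file.path(dir, "genes.gtf"), file.path(dir, "genome.fa"))
  o1 <- g1$transcripts[order(g1$transcripts$transcript_id), ]
  o2 <- g2$transcripts[order(g2$transcripts$transcript_id), ]
  expect_equal(o1, o2)
})

test_that("every coding call equals whole-protein retranslation over all CDS SNVs", {
  fx <- simulate_genome(seed = 19, n_genes = 10)
  gm <- fx$models
  expect_setequal(unique(gm$transcripts$strand), c("+", "-"))
  for (ti in seq_len(nrow(gm$transcripts))) {
    tx <- gm$transcripts[ti, ]
    cds <- tx$cds[[1]]
    positions <- unlist(mapply(seq, cds$start, cds$end, SIMPLIFY = FALSE))
    chrom_seq <- gm$genome[[tx$chrom]]
    cases <- dplyr::bind_rows(lapply(positions, function(p) {
      ref <- substr(chrom_seq, p, p)
      tibble::tibble(chrom = tx$chrom, pos = p, ref = ref,
                     alt = setdiff(c("A", "C", "G", "T"), ref))
    }))
    got <- classify_variants(cases, gm)
    want <- mapply(function(p, alt) {
      oracle_coding_category(gm, tx$transcript_id, p, alt)
    }, cases$pos, cases$alt)
    expect_equal(got$category, unname(want),
                 label = paste("transcript", tx$transcript_id))
  }
})

test_that("a gene and its reverse-complement mirror classify mirrored variants identically", {
  hg <- hand_genome()
  gm_f <- read_gene_models(hg$gff, hg$fa)
  L <- nchar(hg$seq)
  mirror_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hg$seq)))
  fa_r <- tempfile(fileext = ".fa")
  writeLines(c(">1", mirror_seq), fa_r)
  gff_r <- tempfile(fileext = ".gff3")
  mir <- function(a, b) c(L - b + 1, L - a + 1)
  e1 <- mir(31, 48); e2 <- mir(70, 87)
  writeLines(c(
    "##gff-version 3",
    sprintf("1\ttest\tmRNA\t%d\t%d\t.\t-\t.\tID=t1r", mir(31, 87)[1], mir(31, 87)[2]),
    sprintf("1\ttest\texon\t%d\t%d\t.\t-\t.\tParent=t1r", e2[1], e2[2]),
    sprintf("1\ttest\texon\t%d\t%d\t.\t-\t.\tParent=t1r", e1[1], e1[2]),
    sprintf("1\ttest\tCDS\t%d\t%d\t.\t-\t0\tParent=t1r", e2[1], e2[2]),
    sprintf("1\ttest\tCDS\t%d\t%d\t.\t-\t0\tParent=t1r", e1[1], e1[2])
  ), gff_r)
  gm_r <- read_gene_models(gff_r, fa_r)
  expect_equal(gm_r$transcripts$cds_seq, gm_f$transcripts$cds_seq)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in c(34L, 36L, 37L, 50L, 59L, 5L)) {
    ref <- substr(hg$seq, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    fwd <- classify_variants(mk_variants("1", pos, ref = ref, alt = alt), gm_f)
    rev_pos <- L - pos + 1L
    rev <- classify_variants(
      mk_variants("1", rev_pos, ref = comp[[ref]], alt = comp[[alt]]), gm_r)
    expect_equal(rev$category, fwd$category, label = paste("pos", pos))
  }
})

test_that("the classifier is total: every SNV receives exactly one category", {
  fx <- simulate_genome(seed = 23, n_genes = 3)
  gm <- fx$models
  set.seed(23)
  pos <- sample(nchar(gm$genome[[1]]), 200)
  refs <- vapply(pos, function(p) substr(gm$genome[[1]], p, p), character(1))
  v <- tibble::tibble(chrom = "1", pos = as.integer(pos), ref = refs,
                      alt = vapply(refs, function(r)
                        setdiff(c("A", "C", "G", "T"), r)[1], character(1)))
  calls <- classify_variants(v, gm)
  expect_equal(nrow(calls), 200)
  expect_true(all(calls$category %in%
                    c("regulatory", "splicing", "missense", "synonymous", "nonsense")))
})
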