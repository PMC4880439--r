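# Small in-code fixtures shared across test files.

mk_variants <- function(chrom, pos, ref = "A", alt = "G", ...) {
  tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt, ...)
}

write_tmp_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records
  ), path)
  path
}

write_tmp_scores <- function(lines, tools,
                             path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(c("chrom", "pos", "ref", "alt", tools), collapse = "\t"),
               lines), path)
  path
}

# A two-tool labeled training table with clean Gaussian separation.
mk_training <- function(n_per_class = 100, seed = 42,
                        categories = "missense") {
  specs <- tool_specs(tool_spec("alpha", "higher_is_deleterious"),
                      tool_spec("beta", "lower_is_deleterious"))
  set.seed(seed)
  rows <- lapply(seq_along(categories), function(ci) {
    cat <- categories[ci]
    tibble::tibble(
      chrom = "1",
      pos = seq_len(2 * n_per_class) + 10000L * ci,
      ref = "A", alt = "G",
      label = rep(c("deleterious", "neutral"), each = n_per_class),
      category = cat,
      alpha = c(rnorm(n_per_class, 0.7, 0.1), rnorm(n_per_class, 0.3, 0.1)),
      beta = c(rnorm(n_per_class, 0.3, 0.1), rnorm(n_per_class, 0.7, 0.1))
    )
  })
  score_table(dplyr::bind_rows(rows), specs)
}
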