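#' Remove neutral variants that overlap disease sets
#'
#' Drops every neutral-pool variant whose allele-specific key
#' (`chrom:pos:ref:alt`, chromosome normalized) appears in any of the
#' supplied disease collections, mirroring the filtering of a neutral pool
#' against pathogenic databases. Counts removed per disease set are reported
#' via a message and attached as attribute `n_removed`.
#'
#' @param neutral_pool Variant tibble.
#' @param disease_sets A list of variant tibbles (possibly named).
#' @return The filtered neutral pool (never larger than the input; applying
#'   the filter twice changes nothing).
#' @export
remove_overlaps <- function(neutral_pool, disease_sets) {
  validate_variants(neutral_pool, "neutral_pool")
  pool_keys <- variant_key(neutral_pool)
  drop <- rep(FALSE, nrow(neutral_pool))
  n_removed <- integer(length(disease_sets))
  for (i in seq_along(disease_sets)) {
    ds_keys <- variant_key(disease_sets[[i]])
    hit <- pool_keys %in% ds_keys
    n_removed[i] <- sum(hit & !drop)
    drop <- drop | hit
  }
  if (length(disease_sets) > 0) {
    nm <- names(disease_sets) %||% as.character(seq_along(disease_sets))
    inform(sprintf("remove_overlaps: removed %s (total %d of %d)",
                   paste(sprintf("%d [%s]", n_removed, nm), collapse = ", "),
                   sum(drop), nrow(neutral_pool)))
  }
  out <- neutral_pool[!drop, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

#' Match each deleterious variant to its nearest neutral neighbor
#'
#' Greedy nearest-neighbor matching without replacement: deleterious variants
#' are processed in (chrom, pos) order and each takes the closest unused
#' neutral variant on the same chromosome (ties on distance go to the
#' lower-position candidate). Deleterious variants left without a
#' same-chromosome candidate are dropped with a warning, so the result is an
#' exactly 1:1 balanced matched set. Matching is intended to be run within
#' one category.
#'
#' @param deleterious,neutral_pool Variant tibbles.
#' @return A tibble with one row per matched variant (all input columns,
#'   `label` set), plus `pair_id`, `role` (`"deleterious"`/`"neutral"`) and
#'   `distance` (bp between the pair's members).
#' @export
match_neutral <- function(deleterious, neutral_pool) {
  validate_variants(deleterious, "deleterious")
  validate_variants(neutral_pool, "neutral_pool")
  if (nrow(neutral_pool) == 0) abort("neutral pool is empty")
  del <- deleterious %>%
    mutate(.chrom = norm_chrom(.data$chrom)) %>%
    arrange(.data$.chrom, .data$pos)
  neut <- neutral_pool %>%
    mutate(.chrom = norm_chrom(.data$chrom)) %>%
    arrange(.data$.chrom, .data$pos)

  used <- rep(FALSE, nrow(neut))
  pair_del <- integer(0)
  pair_neut <- integer(0)
  dist <- integer(0)
  for (i in seq_len(nrow(del))) {
    cand <- which(neut$.chrom == del$.chrom[i] & !used)
    if (length(cand) == 0) next
    d <- abs(neut$pos[cand] - del$pos[i])
    # candidates are position-sorted; which.min takes the first = lowest pos
    j <- cand[which.min(d)]
    used[j] <- TRUE
    pair_del <- c(pair_del, i)
    pair_neut <- c(pair_neut, j)
    dist <- c(dist, abs(neut$pos[j] - del$pos[i]))
  }
  n_dropped <- nrow(del) - length(pair_del)
  if (n_dropped > 0) {
    warn(sprintf("match_neutral: dropped %d deleterious variant(s) with no same-chromosome neutral candidate left",
                 n_dropped))
  }
  k <- length(pair_del)
  d_rows <- del[pair_del, , drop = FALSE] %>% select(-".chrom") %>%
    mutate(label = "deleterious", pair_id = seq_len(k),
           role = "deleterious", distance = dist)
  n_rows <- neut[pair_neut, , drop = FALSE] %>% select(-".chrom") %>%
    mutate(label = "neutral", pair_id = seq_len(k),
           role = "neutral", distance = dist)
  bind_rows(d_rows, n_rows) %>% arrange(.data$pair_id, desc(.data$role == "deleterious"))
}

#' Split variants into train/test by submission date
#'
#' Variants dated strictly after the cutoff go to the test set; everything
#' else (including the cutoff date itself) trains. For a matched dataset
#' (rows carrying `pair_id`/`role` from [match_neutral()]) each pair goes
#' wholly to the side of its deleterious member.
#'
#' @param variants Variant tibble; every row needs a `date`.
#' @param cutoff A `Date` (or string coercible to one).
#' @return A list with tibbles `train` and `test`.
#' @export
split_by_date <- function(variants, cutoff) {
  cutoff <- as.Date(cutoff)
  if (!("date" %in% names(variants)) || anyNA(variants$date)) {
    bad <- if ("date" %in% names(variants)) which(is.na(variants$date))[1] else 1L
    abort(sprintf("split_by_date: variant %s:%s has no date",
                  variants$chrom[bad], variants$pos[bad]))
  }
  if (all(c("pair_id", "role") %in% names(variants))) {
    del_dates <- variants %>% filter(.data$role == "deleterious") %>%
      select("pair_id", del_date = "date")
    to_test <- variants %>% left_join(del_dates, by = "pair_id") %>%
      pull(.data$del_date) > cutoff
  } else {
    to_test <- variants$date > cutoff
  }
  if (!any(to_test)) warn("split_by_date: test set is empty (no date after cutoff)")
  list(train = variants[!to_test, , drop = FALSE],
       test = variants[to_test, , drop = FALSE])
}

#' Seeded random train/test split
#'
#' Uniform random partition at the variant level (used for the non-exonic
#' categories when no date rule applies); rows with `pair_id` are kept
#' together on one side.
#'
#' @param variants Variant tibble.
#' @param test_fraction Target test fraction by variant count.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_random <- function(variants, test_fraction, seed) {
  stopifnot(test_fraction >= 0, test_fraction <= 1)
  set.seed(as.integer(seed))
  if ("pair_id" %in% names(variants)) {
    ids <- unique(variants$pair_id)
    test_ids <- sample(ids, round(test_fraction * length(ids)))
    to_test <- variants$pair_id %in% test_ids
  } else {
    to_test <- seq_len(nrow(variants)) %in%
      sample(nrow(variants), round(test_fraction * nrow(variants)))
  }
  list(train = variants[!to_test, , drop = FALSE],
       test = variants[to_test, , drop = FALSE])
}

#' Global pairwise protein sequence identity
#'
#' Needleman–Wunsch global alignment (match 1, mismatch 0, affine gaps:
#' opening 1, extension 0.5 per gapped position), with identity defined as
#' the number of identically aligned residues divided by the length of the
#' shorter sequence — the denominator convention of CD-HIT-style clustering.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) abort("sequences must be non-empty")
  letters <- sort(unique(strsplit(paste0(seq_a, seq_b), "")[[1]]))
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = m, gapOpening = 1, gapExtension = 0.5
  )
  Biostrings::nmatch(aln) / min(nchar(seq_a), nchar(seq_b))
}

#' Greedy identity clustering of protein sequences
#'
#' Sequences are sorted by length descending (ties by id) and each joins the
#' first existing cluster whose representative shares at least `threshold`
#' identity with it, otherwise it founds a new cluster — the greedy scheme of
#' CD-HIT, without its word-filter heuristics.
#'
#' @param sequences Named character vector of protein sequences.
#' @param threshold Identity threshold (default 0.50).
#' @return A tibble with columns `id`, `cluster` (integer), `representative`.
#' @export
cluster_sequences <- function(sequences, threshold = 0.50) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) abort("sequences must have unique names")
  ord <- order(-nchar(sequences), ids)
  reps <- character(0)
  assign <- integer(length(sequences))
  names(assign) <- ids
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(sequences[[i]], sequences[[reps[k]]]) >= threshold) {
        assign[ids[i]] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      assign[ids[i]] <- length(reps)
    }
  }
  tibble(id = ids, cluster = unname(assign), representative = reps[assign])
}

#' Cluster-aware train/test split for exonic variants
#'
#' Protein sequences are clustered greedily at `threshold` identity and whole
#' clusters are assigned to the test side by seeded shuffle until the target
#' test fraction (by variant count) is reached or passed, so that variants in
#' similar proteins never straddle the split.
#'
#' @param variants Variant tibble with a `protein_id` column mapping each
#'   variant to a sequence id.
#' @param sequences Named character vector of protein sequences covering
#'   every `protein_id`.
#' @param threshold Identity threshold (default 0.50).
#' @param test_fraction Target test fraction by variant count.
#' @param seed Integer seed for the cluster shuffle.
#' @return A list with tibbles `train` and `test` and the `clusters` tibble.
#' @export
cluster_split_exonic <- function(variants, sequences, threshold = 0.50,
                                 test_fraction = 0.25, seed = 1) {
  if (!("protein_id" %in% names(variants))) {
    abort("variants need a `protein_id` column for the exonic split")
  }
  unmapped <- setdiff(unique(variants$protein_id), names(sequences))
  if (length(unmapped) > 0 || anyNA(variants$protein_id)) {
    abort(sprintf("variant(s) map to no sequence: %s",
                  paste(c(unmapped, if (anyNA(variants$protein_id)) "<NA>"),
                        collapse = ", ")))
  }
  clusters <- cluster_sequences(sequences, threshold)
  cl_of <- stats::setNames(clusters$cluster, clusters$id)
  v_cl <- unname(cl_of[variants$protein_id])

  counts <- table(v_cl)
  cl_ids <- as.integer(names(counts))
  set.seed(as.integer(seed))
  shuffled <- sample(cl_ids)
  target <- test_fraction * nrow(variants)
  test_cl <- integer(0)
  got <- 0
  for (cl in shuffled) {
    if (got >= target) break
    test_cl <- c(test_cl, cl)
    got <- got + counts[[as.character(cl)]]
  }
  to_test <- v_cl %in% test_cl
  list(train = variants[!to_test, , drop = FALSE],
       test = variants[to_test, , drop = FALSE],
       clusters = clusters)
}
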