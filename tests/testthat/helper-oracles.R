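# Independent oracles used to cross-check the package implementations.
# Each is a deliberately naive, direct transcription of the definition.

# Exhaustive threshold search: same candidate set and tie-break definition as
# the learner, evaluated by direct comparison per candidate.
oracle_threshold <- function(scores, labels, polarity = "higher_is_deleterious") {
  is_d <- labels %in% c("deleterious", "D")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  evals <- vapply(cand, function(t) {
    pred_d <- if (polarity == "higher_is_deleterious") scores >= t else scores <= t
    sens <- sum(pred_d & is_d) / sum(is_d)
    spec <- sum(!pred_d & !is_d) / sum(!is_d)
    (sens + spec) / 2
  }, numeric(1))
  best <- max(evals)
  ties <- cand[evals == best]
  thr <- if (polarity == "higher_is_deleterious") min(ties) else max(ties)
  list(threshold = thr, normalized_accuracy = best)
}

# O(n^2) pairwise AUC: P(score_D > score_N) + 0.5 P(equal).
oracle_auc <- function(scores, labels, polarity = "higher_is_deleterious") {
  is_d <- labels %in% c("deleterious", "D")
  s <- if (polarity == "higher_is_deleterious") scores else -scores
  d <- s[is_d]; n <- s[!is_d]
  tot <- 0
  for (x in d) tot <- tot + sum(x > n) + 0.5 * sum(x == n)
  tot / (length(d) * length(n))
}

# Gotoh affine-gap global alignment score: match 1, mismatch 0, a gap of
# length L costs 1 + 0.5 * L (opening 1 plus 0.5 per gapped position).
oracle_align_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  open <- 1.5; ext <- 0.5  # first gap position pays opening + extension
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(1 + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(1 + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (a[i - 1] == b[j - 1]) 1 else 0
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Whole-CDS retranslation classifier for coding SNVs: substitute the allele
# in the chromosome, re-extract the spliced CDS, translate both proteins
# with Biostrings::translate, and compare. Independent of the codon-local
# classifier path.
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_translate <- function(s) {
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

oracle_coding_category <- function(models, transcript_id, pos, alt) {
  k <- which(models$transcripts$transcript_id == transcript_id)
  strand <- models$transcripts$strand[k]
  iv <- models$transcripts$cds[[k]]
  chrom_seq <- models$genome[[models$transcripts$chrom[k]]]
  extract <- function(seqchr) {
    s <- paste(substring(seqchr, iv$start, iv$end), collapse = "")
    if (strand == "-") s <- oracle_revcomp(s)
    oracle_translate(s)
  }
  p_ref <- extract(chrom_seq)
  mut <- chrom_seq
  substr(mut, pos, pos) <- alt
  p_alt <- extract(mut)
  if (p_alt == p_ref) return("synonymous")
  aa_ref <- strsplit(p_ref, "")[[1]]
  aa_alt <- strsplit(p_alt, "")[[1]]
  k <- which(aa_ref != aa_alt)[1]
  if (aa_alt[k] == "*" && aa_ref[k] != "*") "nonsense" else "missense"
}

# Literal re-execution of the stated greedy matching rule, written as a
# direct loop over (chrom, pos)-ordered deleterious variants.
oracle_greedy_match <- function(del, neut) {
  del <- del[order(del$chrom, del$pos), ]
  neut <- neut[order(neut$chrom, neut$pos), ]
  taken <- rep(FALSE, nrow(neut))
  out <- list()
  for (i in seq_len(nrow(del))) {
    idx <- which(neut$chrom == del$chrom[i] & !taken)
    if (length(idx) == 0) next
    dists <- abs(neut$pos[idx] - del$pos[i])
    best <- idx[dists == min(dists)]
    j <- best[which.min(neut$pos[best])]  # tie -> lower position
    taken[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      del_pos = del$pos[i], neut_pos = neut$pos[j],
      distance = abs(neut$pos[j] - del$pos[i]))
  }
  do.call(rbind, out)
}
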