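test_that("overlap filtering is allele-specific, shrinking, and idempotent", {
  pool <- mk_variants("1", 1:5)
  disease <- list(cosmic = mk_variants("1", c(2L, 4L)),
                  gwas = mk_variants("1", 2L, alt = "T"))  # other allele
  out <- suppressMessages(remove_overlaps(pool, disease))
  expect_equal(out$pos, c(1L, 3L, 5L))
  expect_equal(attr(out, "n_removed"), c(2L, 0L))
  # empty disease sets: identity
  expect_equal(nrow(remove_overlaps(pool, list())), 5)
  # idempotence
  again <- suppressMessages(remove_overlaps(out, disease))
  expect_equal(again$pos, out$pos)
})

test_that("matching takes the nearest neutral, without replacement, dropping leftovers", {
  del <- mk_variants("1", 1000L)
  neut <- mk_variants("1", c(900L, 1200L))
  pairs <- match_neutral(del, neut)
  expect_equal(pairs$pos[pairs$role == "neutral"], 900L)
  expect_equal(unique(pairs$distance), 100L)

  del2 <- mk_variants("1", c(1000L, 1010L))
  neut2 <- mk_variants("1", 1005L)
  expect_warning(p2 <- match_neutral(del2, neut2), "dropped 1")
  expect_equal(nrow(p2), 2)
  expect_equal(p2$pos, c(1000L, 1005L))
  expect_equal(unique(p2$distance), 5L)
  expect_error(match_neutral(del, neut[0, ]), "empty")
})

test_that("greedy matching equals an independent execution of the stated rule", {
  set.seed(41)
  for (rep in 1:40) {
    nd <- sample(1:8, 1); nn <- sample(1:8, 1)
    del <- mk_variants(sample(c("1", "2"), nd, replace = TRUE),
                       sample(1:500, nd))
    neut <- mk_variants(sample(c("1", "2"), nn, replace = TRUE),
                        sample(1:500, nn))
    got <- suppressWarnings(match_neutral(del, neut))
    want <- oracle_greedy_match(as.data.frame(del), as.data.frame(neut))
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$pos[got$role == "deleterious"], want$del_pos)
      expect_equal(got$pos[got$role == "neutral"], want$neut_pos)
      expect_equal(got$distance[got$role == "deleterious"], want$distance)
    }
    # 1:1 balance, no neutral reuse
    expect_equal(sum(got$role == "deleterious"), sum(got$role == "neutral"))
    neut_keys <- variant_key(got[got$role == "neutral", ])
    expect_equal(anyDuplicated(neut_keys), 0)
  }
})

test_that("the date split is strict ('after' the cutoff) and pair-aware", {
  v <- mk_variants("1", 1:3,
                   date = as.Date(c("2015-03-01", "2014-12-31", "2012-01-01")))
  sp <- split_by_date(v, "2014-12-31")
  expect_equal(sp$test$pos, 1L)
  expect_equal(sort(sp$train$pos), c(2L, 3L))

  expect_warning(all_train <- split_by_date(
    mk_variants("1", 1:2, date = as.Date("2010-01-01")), "2014-12-31"),
    "empty")
  expect_equal(nrow(all_train$test), 0)
  expect_error(split_by_date(mk_variants("1", 1L), "2014-12-31"), "no date")

  # a matched pair follows its deleterious member even if the neutral is older
  del <- mk_variants("1", 100L, date = as.Date("2015-06-01"))
  neut <- mk_variants("1", 90L, date = as.Date("2010-01-01"))
  pairs <- match_neutral(del, neut)
  sp2 <- split_by_date(pairs, "2014-12-31")
  expect_equal(nrow(sp2$test), 2)
  expect_equal(nrow(sp2$train), 0)
})

test_that("pairwise identity matches the independent alignment oracle", {
  expect_equal(pairwise_identity("MKVL", "MKVL"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_error(pairwise_identity("", "MK"), "non-empty")

  # ungapped optimum: 7 identical of 10 (shorter length 10)
  a <- "MKTAYIAKQR"; b <- "MKTAYIYYYR"
  expect_equal(pairwise_identity(a, b), 7 / 10)

  # the alignment engine agrees with a hand-rolled Gotoh DP on the score
  cases <- list(c("MKTAYIAKQR", "MKTAYIYYYR"), c("MKTAYIAKQR", "MKTAYIKQR"),
                c("ACDEFGHIKL", "ACDFGHIKL"), c("MMMM", "MM"))
  for (cs in cases) {
    m <- diag(1, 26); dimnames(m) <- list(LETTERS, LETTERS)
    aln <- Biostrings::pairwiseAlignment(cs[1], cs[2], type = "global",
                                         substitutionMatrix = m,
                                         gapOpening = 1, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), oracle_align_score(cs[1], cs[2]))
  }
  # one-residue deletion aligns perfectly elsewhere: identity 1 by the
  # shorter-sequence denominator
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIKQR"), 1.0)
})

test_that("greedy clustering reproduces a hand-executed fixture", {
  seqs <- c(
    s1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",   # 33 aa
    s2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",   # ~97% id to s1
    s3 = "MKTAYIAKQRQISFVKSH",                  # prefix of s1 (18 aa)
    s4 = "WWWWWWWWWWWWWWWWWWWWWWWWWWWWWW",      # unrelated, 30 aa
    s5 = "WWWWWWWWWWWWWWWWWWWWWWWWWWWWWA",      # ~97% id to s4
    s6 = "GGGGG"                                # unrelated, short
  )
  cl <- cluster_sequences(seqs, threshold = 0.5)
  # length order: s1, s2 (33), s4, s5 (30), s3 (18), s6 (5)
  by_id <- setNames(cl$cluster, cl$id)
  expect_equal(by_id[["s1"]], by_id[["s2"]])
  expect_equal(by_id[["s1"]], by_id[["s3"]])  # prefix: 18/18 identity to s1
  expect_equal(by_id[["s4"]], by_id[["s5"]])
  expect_false(by_id[["s1"]] == by_id[["s4"]])
  expect_false(by_id[["s6"]] %in% c(by_id[["s1"]], by_id[["s4"]]))
  expect_equal(cl$representative[cl$id == "s3"], "s1")
})

test_that("the exonic split never separates same-cluster variants", {
  seqs <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQ", p2 = "MKTAYIAKQRQISFVKSHFSRA",
            p3 = "WWWWWWWWWWWWWWWWWWWW", p4 = "GGGGGGGGGGGGGGGGGGGG",
            p5 = "HHHHHHHHHHHHHHHHHHHH")
  v <- mk_variants("1", 1:20,
                   protein_id = rep(c("p1", "p2", "p3", "p4", "p5"), 4))
  sp <- cluster_split_exonic(v, seqs, threshold = 0.5, test_fraction = 0.4,
                             seed = 7)
  expect_equal(nrow(sp$train) + nrow(sp$test), 20)
  cl_of <- setNames(sp$clusters$cluster, sp$clusters$id)
  train_cl <- unique(cl_of[sp$train$protein_id])
  test_cl <- unique(cl_of[sp$test$protein_id])
  expect_equal(length(intersect(train_cl, test_cl)), 0)
  expect_error(cluster_split_exonic(mk_variants("1", 1L, protein_id = "zz"),
                                    seqs), "map to no sequence")
  # identical proteins always co-locate
  expect_equal(cl_of[["p1"]], cl_of[["p2"]])
  # all-dissimilar: singleton clusters, split reachable within one cluster
  v2 <- mk_variants("1", 1:3, protein_id = c("p3", "p4", "p5"))
  sp2 <- cluster_split_exonic(v2, seqs[3:5], test_fraction = 1 / 3, seed = 1)
  expect_equal(nrow(sp2$test), 1)
})

test_that("seeded random splits are reproducible and pair-preserving", {
  v <- mk_variants("1", 1:40, pair_id = rep(1:20, each = 2))
  a <- split_random(v, 0.25, seed = 3)
  b <- split_random(v, 0.25, seed = 3)
  expect_identical(a, b)
  # no pair straddles the split
  expect_equal(length(intersect(a$train$pair_id, a$test$pair_id)), 0)
  expect_equal(nrow(a$test), 10)  # 5 pairs
})
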