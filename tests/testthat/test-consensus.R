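test_that("weighted vote follows the stated arithmetic, ties go to D", {
  v <- consensus_score(c("D", "D", "N"), c(80, 60, 70))
  expect_equal(v$score, (0.8 + 0.6 - 0.7) / 2.1)
  expect_equal(v$prediction, "D")

  single <- consensus_score("N", 90)
  expect_equal(single$score, -1.0)
  expect_equal(single$prediction, "N")

  tie <- consensus_score(c("D", "N"), c(50, 50))
  expect_equal(tie$score, 0)
  expect_equal(tie$prediction, "D")

  zero <- consensus_score(c("D", "N"), c(0, 0))
  expect_equal(zero$score, 0)
  expect_error(consensus_score(character(), integer()), "at least one vote")
})

test_that("the vote is permutation-symmetric, bounded, and sign-antisymmetric", {
  set.seed(21)
  for (rep in 1:50) {
    k <- sample(1:7, 1)
    pred <- sample(c("D", "N"), k, replace = TRUE)
    conf <- sample(0:99, k, replace = TRUE)
    s <- consensus_score(pred, conf)$score
    expect_gte(s, -1); expect_lte(s, 1)
    perm <- sample(k)
    expect_equal(consensus_score(pred[perm], conf[perm])$score, s)
    flipped <- ifelse(pred == "D", "N", "D")
    expect_equal(consensus_score(flipped, conf)$score, -s)
  }
})

test_that("equal confidences reduce the vote to an unweighted majority", {
  set.seed(22)
  for (rep in 1:30) {
    k <- sample(c(3, 5, 7), 1)
    pred <- sample(c("D", "N"), k, replace = TRUE)
    v <- consensus_score(pred, rep(60, k))
    maj <- if (sum(pred == "D") > k / 2) "D" else if (sum(pred == "D") < k / 2) "N" else "D"
    expect_equal(v$prediction, maj)
  }
})

test_that("subset selection scans all 26 subsets of 5 tools and excludes noise", {
  specs <- tool_specs(
    tool_spec("strong"), tool_spec("junk1"), tool_spec("junk2")
  )
  set.seed(31)
  n <- 150
  train <- score_table(tibble::tibble(
    chrom = "1", pos = 1:(2 * n), ref = "A", alt = "G",
    label = rep(c("deleterious", "neutral"), each = n),
    category = "missense",
    strong = c(rnorm(n, 0.8, 0.08), rnorm(n, 0.2, 0.08)),
    junk1 = runif(2 * n),
    junk2 = runif(2 * n)
  ), specs)
  model <- fit_thresholds(train, specs, n_bins = 20, window = 5)
  cm <- select_consensus_subset(train, model, "missense", specs,
                                n_bins = 20, window = 5)
  # exhaustive scan of all subsets of size >= 2 (2^3 - 3 - 1 = 4 for T=3)
  expect_equal(nrow(cm$subset_scan), 4)
  expect_true("strong" %in% cm$tools)
  expect_true(length(setdiff(c("junk1", "junk2"), cm$tools)) >= 1)
  all_na <- cm$subset_scan$normalized_accuracy[cm$subset_scan$size == 3]
  expect_gte(cm$train_normalized_accuracy, all_na)
  expect_equal(cm$best_single$tool, "strong")
})

test_that("T=5 tools yield exactly 26 evaluated subsets", {
  expect_equal(sum(choose(5, 2:5)), 26)
  tbl <- mk_training(n_per_class = 80)
  specs5 <- tool_specs(
    tool_spec("alpha"), tool_spec("beta", "lower_is_deleterious"),
    tool_spec("gamma"), tool_spec("delta"), tool_spec("epsilon")
  )
  set.seed(33)
  tbl$gamma <- tbl$alpha + rnorm(nrow(tbl), 0, 0.05)
  tbl$delta <- tbl$alpha + rnorm(nrow(tbl), 0, 0.05)
  tbl$epsilon <- tbl$alpha + rnorm(nrow(tbl), 0, 0.05)
  tbl <- score_table(tbl, specs5)
  model <- fit_thresholds(tbl, specs5, n_bins = 10, window = 3)
  cm <- select_consensus_subset(tbl, model, "missense", specs5,
                                n_bins = 10, window = 3)
  expect_equal(nrow(cm$subset_scan), 26)
})

test_that("when all tools vote identically the 2-tool lexicographic subset wins", {
  specs <- tool_specs(tool_spec("b_tool"), tool_spec("c_tool"), tool_spec("a_tool"))
  set.seed(35)
  n <- 60
  base <- c(rnorm(n, 0.75, 0.1), rnorm(n, 0.25, 0.1))
  train <- score_table(tibble::tibble(
    chrom = "1", pos = 1:(2 * n), ref = "A", alt = "G",
    label = rep(c("deleterious", "neutral"), each = n),
    category = "splicing",
    b_tool = base, c_tool = base, a_tool = base
  ), specs)
  model <- fit_thresholds(train, specs, n_bins = 10, window = 3)
  cm <- select_consensus_subset(train, model, "splicing", specs,
                                n_bins = 10, window = 3)
  expect_equal(cm$tools, c("a_tool", "b_tool"))
})

test_that("consensus recalibration separates separable consensus scores", {
  cs <- c(seq(0.2, 1, length.out = 30), seq(-1, -0.2, length.out = 30))
  lb <- rep(c("deleterious", "neutral"), each = 30)
  cal <- calibrate_consensus(cs, lb, n_bins = 10, window = 3)
  expect_equal(cal$normalized_accuracy, 1.0)
  expect_error(calibrate_consensus(rep(0.5, 20), rep(c("D", "N"), 10)))
})

test_that("prediction equals a step-by-step hand pipeline and renormalizes missing votes", {
  tbl <- mk_training(n_per_class = 80)
  specs <- get_tool_specs(tbl)
  bundle <- train_model(tbl, specs, n_bins = 10, window = 3,
                        select_subsets = FALSE)
  query <- tbl[c(1, 5, 100), ]
  scores <- tbl
  scores$beta[which(variant_key(scores) == variant_key(query)[2])] <- NA
  preds <- predict_variants(query, scores, bundle)

  cm <- bundle$consensus$missense
  for (i in seq_len(nrow(query))) {
    votes <- lapply(cm$tools, function(tl) {
      raw <- scores[[tl]][variant_key(scores) == variant_key(query)[i]]
      transform_score(bundle$thresholds$curves[[paste0(tl, "|missense")]], raw)
    })
    vt <- dplyr::bind_rows(votes)
    ok <- !is.na(vt$prediction)
    hand <- consensus_score(vt$prediction[ok], vt$confidence[ok])
    expect_equal(preds$consensus_score[i], hand$score)
    hand_tr <- transform_score(cm$curve, hand$score)
    expect_equal(preds$consensus_prediction[i], hand_tr$prediction)
    expect_equal(preds$consensus_confidence[i], hand_tr$confidence)
  }
  # variant 2 had only one available vote: score is +/-1 of that vote
  expect_true(abs(preds$consensus_score[2]) == 1)
})

test_that("variants with no scores at all are flagged NO_SCORES", {
  tbl <- mk_training(n_per_class = 50)
  bundle <- train_model(tbl, get_tool_specs(tbl), n_bins = 10, window = 3,
                        select_subsets = FALSE)
  orphan <- mk_variants("9", 1L, category = "missense")
  preds <- predict_variants(orphan, tbl, bundle)
  expect_true(preds$no_scores)
  expect_true(is.na(preds$consensus_prediction))
  expect_error(predict_variants(mk_variants("9", 1L, category = "nonsense"),
                                tbl, bundle), "nonsense")
})

test_that("five independent tools at 0.7 balanced accuracy beat any single tool", {
  set.seed(99)
  n <- 10000
  truth <- rep(c("D", "N"), each = n / 2)
  correct <- matrix(runif(n * 5) < 0.7, n, 5)
  votes <- ifelse(correct, truth, ifelse(truth == "D", "N", "D"))
  cons <- vapply(seq_len(n), function(i) {
    consensus_score(votes[i, ], rep(50, 5))$prediction
  }, character(1))
  acc_cons <- confusion_metrics(cons, truth)$normalized_accuracy
  acc_tools <- apply(votes, 2, function(v) {
    confusion_metrics(v, truth)$normalized_accuracy
  })
  p_major <- pbinom(2, 5, 0.7, lower.tail = FALSE)
  expect_lt(abs(acc_cons - p_major), 0.02)
  expect_gt(acc_cons, max(acc_tools))
})
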