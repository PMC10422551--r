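test_that("information gain is maximal for a perfect separator, zero for noise", {
  set.seed(21)
  n <- 30L
  co <- data.frame(
    perfect = c(rnorm(15, 0, 0.5), rnorm(15, 10, 0.5)),
    constant = rep(1, n),
    group = rep(c("LowFlex", "HighFlex"), each = 15),
    check.names = FALSE
  )
  co$shuffled <- sample(co$perfect)  # label-independent permutation
  rk <- rank_features(co)
  expect_identical(rk$feature[1], "perfect")
  expect_equal(rk$score[rk$feature == "perfect"], 1)  # 1 bit, balanced groups
  expect_equal(rk$score[rk$feature == "constant"], 0)
  expect_lt(rk$score[rk$feature == "shuffled"], 0.35)

  # duplicated features earn identical scores and adjacent ranks
  co$copy <- co$perfect
  rk2 <- rank_features(co)
  expect_identical(rk2$feature[1:2], c("copy", "perfect"))  # alphabetical tie
  expect_equal(rk2$score[1], rk2$score[2])
})

test_that("ranking score equals a brute-force entropy computation", {
  set.seed(22)
  x <- rnorm(20)
  y <- rep(c("HighFlex", "LowFlex"), 10)
  co <- data.frame(x = x, group = y)
  rk <- rank_features(co)
  # brute force over every midpoint
  ent <- function(l) { p <- table(l) / length(l); p <- p[p > 0]; -sum(p * log2(p)) }
  xs <- sort(unique(x))
  gains <- vapply(seq_len(length(xs) - 1), function(i) {
    thr <- (xs[i] + xs[i + 1]) / 2
    left <- y[x <= thr]; right <- y[x > thr]
    ent(y) - (length(left) * ent(left) + length(right) * ent(right)) / 20
  }, numeric(1))
  expect_equal(rk$score, max(gains), tolerance = 1e-12)
})

test_that("select_top_k subsets columns in rank order", {
  co <- generate_rule_cohort(seed = 2L)
  rk <- rank_features(co)
  top2 <- select_top_k(rk, 2, co)
  expect_identical(setdiff(names(top2), c("subject_id", "group", "CFI")),
                   rk$feature[1:2])
  all_k <- select_top_k(rk, nrow(rk), co)
  expect_setequal(names(all_k), names(co))
  expect_error(select_top_k(rk, 0, co), "positive")
  expect_error(select_top_k(rk, nrow(rk) + 1, co), "exceeds")
})

test_that("all four classifiers are perfect on a 10-SD-separated cohort", {
  co <- generate_separated_cohort(15, 2, 10, seed = 3L)
  res <- compare_classifiers(co, seed = 3L)
  for (m in names(res)) {
    expect_equal(res[[m]]$ca, 1.0, info = m)
    expect_equal(res[[m]]$auc, 1.0, info = m)
    expect_equal(res[[m]]$f1, 1.0, info = m)
    expect_identical(sum(res[[m]]$confusion_matrix), 30L)
  }
})

test_that("LOOCV results are invariant to subject ordering", {
  co <- generate_rule_cohort(seed = 5L)
  r1 <- loocv_evaluate(co, classifier_spec("kNN", seed = 1L))
  perm <- sample(seq_len(nrow(co)))
  r2 <- loocv_evaluate(co[perm, ], classifier_spec("kNN", seed = 1L))
  expect_equal(r1$ca, r2$ca)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$confusion_matrix, r2$confusion_matrix)
})

test_that("metrics recompute exactly from the stored confusion and scores", {
  co <- generate_rule_cohort(seed = 6L)
  for (m in c("kNN", "NaiveBayes")) {
    r <- loocv_evaluate(co, classifier_spec(m, seed = 2L))
    again <- confusion_metrics(r$confusion_matrix)
    expect_identical(r$ca, again$ca)
    expect_identical(r$f1, again$f1)
    expect_identical(r$precision, again$precision)
    expect_identical(r$recall, again$recall)
    expect_identical(r$auc, auc_score(r$actual, r$scores, r$positive))
  }
})

test_that("confusion metrics match hand evaluation of their definitions", {
  cm <- matrix(c(9L, 2L, 1L, 8L), 2, 2,
               dimnames = list(c("HighFlex", "LowFlex"),
                               c("HighFlex", "LowFlex")))
  m <- confusion_metrics(cm)
  expect_equal(m$ca, 0.85)
  # per-class precision 9/11 and 8/9, recall 0.9 and 0.8, equal supports
  expect_equal(m$precision, (9 / 11 + 8 / 9) / 2)
  expect_equal(m$recall, 0.85)
  f_high <- 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9)
  f_low <- 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8)
  expect_equal(m$f1, (f_high + f_low) / 2)
})

test_that("rank-based AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  labels <- rep(c("HighFlex", "LowFlex"), each = 20)
  scores <- c(rnorm(20, 0.6, 0.25), rnorm(20, 0.4, 0.25))
  ours <- auc_score(labels, scores, "HighFlex")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("LowFlex", "HighFlex"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("permuted labels on structureless features give chance accuracy", {
  set.seed(44)
  cas <- replicate(60, {
    co <- generate_separated_cohort(15, 2, 0, seed = sample.int(1e6, 1))
    co$group <- sample(co$group)
    loocv_evaluate(co, classifier_spec("kNN", seed = 1L))$ca
  })
  expect_gte(mean(cas), 0.35)
  expect_lte(mean(cas), 0.65)
})

test_that("decision tree recovers a one-dimensional threshold rule", {
  set.seed(55)
  x <- c(runif(20, 10, 33), runif(20, 37, 60))
  co <- data.frame(x = x, group = ifelse(x > 35, "LowFlex", "HighFlex"))
  tree <- fit_decision_tree(co)
  expect_identical(tree$root$type, "split")
  expect_identical(tree$root$feature, "x")
  expect_gt(tree$root$threshold, 33)
  expect_lt(tree$root$threshold, 37)
  expect_identical(tree_depth(tree), 1L)
  expect_identical(predict(tree, co), co$group)
})

test_that("tree root split matches an independent information-gain fit", {
  skip_if_not_installed("rpart")
  co <- generate_rule_cohort(seed = 9L)
  tree <- fit_decision_tree(co, max_depth = 2L)
  ref <- rpart::rpart(
    factor(group) ~ `RMS RSP Rate` + `Max HR`,
    data = co, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(maxdepth = 2, minsplit = 4, cp = 0.01))
  ref_root_var <- as.character(ref$frame$var[1])
  expect_identical(tree$root$feature, ref_root_var)
  ref_thr <- ref$splits[1, "index"]
  expect_equal(tree$root$threshold, unname(ref_thr), tolerance = 0.15)
})

test_that("two-feature rule cohorts are recovered as depth-2 rule trees", {
  hits_rank <- 0L; hits_tree <- 0L
  reps <- 30L
  for (s in seq_len(reps)) {
    co <- generate_rule_cohort(seed = 1000L + s)
    rk <- rank_features(co)
    if (setequal(rk$feature[1:2], c("RMS RSP Rate", "Max HR"))) {
      hits_rank <- hits_rank + 1L
    }
    tree <- fit_decision_tree(co, max_depth = 2L)
    if (tree$root$type == "split" &&
        tree$root$feature == "RMS RSP Rate" &&
        tree_depth(tree) == 2L &&
        tree$root$threshold > 33 && tree$root$threshold < 37) {
      hits_tree <- hits_tree + 1L
    }
  }
  expect_gte(hits_rank / reps, 0.9)
  expect_gte(hits_tree / reps, 0.9)
})

test_that("pure single-class input collapses to one leaf with proportion 1", {
  co <- data.frame(x = rnorm(10), group = rep("HighFlex", 10))
  tree <- fit_decision_tree(co)
  expect_identical(tree$root$type, "leaf")
  expect_equal(unname(tree$root$proportions["HighFlex"]), 1)
})

test_that("feature reduction to the generating pair does not hurt accuracy", {
  # all features -> top-10 -> top-2 on rule cohorts: mean LOOCV accuracy
  # must not decrease along the reduction (the reduced-model effect)
  reps <- 25L
  ca <- matrix(NA_real_, reps, 3,
               dimnames = list(NULL, c("all", "top10", "top2")))
  for (s in seq_len(reps)) {
    co <- generate_rule_cohort(seed = 2000L + s)
    rk <- rank_features(co)
    for (set in colnames(ca)) {
      feats <- switch(set, all = rk$feature,
                      top10 = rk$feature[1:10], top2 = rk$feature[1:2])
      ca[s, set] <- loocv_evaluate(co, classifier_spec("kNN", seed = 1L),
                                   features = feats)$ca
    }
  }
  expect_gte(mean(ca[, "top10"]), mean(ca[, "all"]) - 0.02)
  expect_gte(mean(ca[, "top2"]), mean(ca[, "top10"]) - 0.02)
  expect_gt(mean(ca[, "top2"]), mean(ca[, "all"]))
})

test_that("degenerate folds and missing features are rejected", {
  co <- generate_separated_cohort(2, 2, 10, seed = 1L)
  expect_error(loocv_evaluate(co, classifier_spec("kNN")), "at least 6")
  co2 <- generate_separated_cohort(15, 2, 10, seed = 1L)
  co2$f1[3] <- NA
  expect_error(loocv_evaluate(co2, classifier_spec("kNN")), "missing")
})
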