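test_that("median split dichotomizes cleanly and balances ties", {
  expect_identical(median_split(c(1, 2, 3, 4)),
                   c("LowFlex", "LowFlex", "HighFlex", "HighFlex"))

  set.seed(2)
  scores <- sample(seq(40, 98, by = 2), 30)  # 30 distinct scores
  lab <- median_split(scores)
  expect_equal(as.integer(table(lab)), c(15L, 15L))

  tied <- median_split(c(1, 2, 2, 3))
  expect_lte(abs(sum(tied == "HighFlex") - sum(tied == "LowFlex")), 1L)

  # enumeration over tie-heavy configurations: sizes always within 1
  for (k in 1:5) {
    sc <- c(rep(2, k), 1, 3, 4)
    lab <- median_split(sc)
    expect_lte(abs(sum(lab == "HighFlex") - sum(lab == "LowFlex")), 1L)
  }

  expect_error(median_split(c(5, 5, 5, 5)), "degenerate")
  expect_error(median_split(c(1, 2, 3)), "at least 4")
})

test_that("normality screens pass normal data and flag skewed data", {
  set.seed(31)
  normal <- rnorm(500)
  res <- normality_tests(normal)
  expect_gt(res$ks$p_value, 0.01)
  expect_gt(res$shapiro$p_value, 0.01)

  skewed <- rexp(500)^2
  res2 <- normality_tests(skewed)
  expect_lt(res2$shapiro$p_value, 0.01)
  expect_lt(res2$ks$p_value, 0.01)

  expect_true(normality_tests(rep(1, 10))$degenerate)
  expect_error(normality_tests(c(1, 2)), "n >= 3")
})

test_that("summary-mode t-test reproduces the published group contrasts", {
  erq <- t_test_from_summary(32.07, 5.28, 15, 27.4, 4.37, 15)
  expect_equal(erq$t_statistic, 2.64, tolerance = 0.01 / 2.64)
  expect_identical(erq$df, 28L)
  expect_equal(erq$cohens_d, 0.97, tolerance = 0.011 / 0.97)
  expect_lt(erq$p_two_tailed, 0.05)

  lfhf <- t_test_from_summary(1.48, 0.49, 14, 2.02, 1.02, 13)
  expect_equal(lfhf$t_statistic, -1.78, tolerance = 0.01 / 1.78)
  expect_identical(lfhf$df, 25L)
  expect_equal(lfhf$cohens_d, -0.69, tolerance = 0.011 / 0.69)

  eq <- t_test_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$cohens_d, 0)
  expect_equal(eq$p_two_tailed, 1)
})

test_that("summary mode agrees with Student's t-test on raw data", {
  set.seed(12)
  a <- rnorm(14, 10, 2); b <- rnorm(13, 11, 3)
  ours <- t_test_from_summary(mean(a), sd(a), 14, mean(b), sd(b), 13)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, as.integer(ref$parameter))
})

test_that("t is antisymmetric under group exchange; preconditions enforced", {
  fwd <- t_test_from_summary(10, 2, 12, 8, 3, 9)
  rev <- t_test_from_summary(8, 3, 9, 10, 2, 12)
  expect_equal(fwd$t_statistic, -rev$t_statistic)
  expect_equal(fwd$cohens_d, -rev$cohens_d)
  expect_equal(fwd$p_two_tailed, rev$p_two_tailed)
  expect_equal(sign(fwd$t_statistic), sign(fwd$mean_high - fwd$mean_low))
  expect_error(t_test_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
  expect_error(t_test_from_summary(1, 0, 5, 2, 0, 5), "not both 0")
})

test_that("cohort-mode tests equal summary mode fed the same moments", {
  co <- generate_cohort(list(
    group_spec("HighFlex", 15, list("ERQ R" = c(32.07, 5.28))),
    group_spec("LowFlex", 15, list("ERQ R" = c(27.4, 4.37)))), seed = 3L)
  tab <- t_test_table(co)
  a <- co[co$group == "HighFlex", "ERQ R"]
  b <- co[co$group == "LowFlex", "ERQ R"]
  man <- t_test_from_summary(mean(a), sd(a), 15, mean(b), sd(b), 15)
  expect_equal(tab$t_statistic, man$t_statistic, tolerance = 1e-9)
  expect_equal(tab$p_two_tailed, man$p_two_tailed, tolerance = 1e-9)
  expect_equal(tab$cohens_d, man$cohens_d, tolerance = 1e-9)
})

test_that("missing values reduce the per-feature degrees of freedom", {
  co <- generate_cohort(list(
    group_spec("HighFlex", 10, list(x = c(5, 1))),
    group_spec("LowFlex", 10, list(x = c(4, 1)))), seed = 6L)
  co$x[1] <- NA
  tab <- t_test_table(co)
  expect_identical(tab$df, 17L)
  expect_identical(tab$n_high + tab$n_low, 19L)
})

test_that("identical groups give t = 0 and skipping is warned for", {
  co <- generate_cohort(list(
    group_spec("HighFlex", 6, list(x = c(2, 1), y = c(1, 0))),
    group_spec("LowFlex", 6, list(x = c(2, 1), y = c(1, 0)))), seed = 8L)
  co$x[co$group == "LowFlex"] <- co$x[co$group == "HighFlex"]
  expect_warning(tab <- t_test_table(co), "zero variance")
  expect_equal(tab$t_statistic[tab$feature_name == "x"], 0)
})

test_that("published summary tables are internally consistent (SE = SD/sqrt n)", {
  tab <- reference_summary_tables("both")
  chk <- summary_se_consistency(tab)
  # every row passes directly except the skin-conductance block, whose
  # printed SE and SD are exactly transposed (printed SE = SD * sqrt(n))
  expect_true(all(chk$status %in% c("ok", "transposed")))
  bad <- chk[chk$status == "transposed", ]
  expect_identical(sort(unique(bad$measure)),
                   c("Mean SC", "RMS SC", "StD SC"))
  expect_identical(nrow(bad), 6L)
  swapped_ok <- abs(bad$se / sqrt(bad$n) - bad$sd) <= 0.011
  expect_true(all(swapped_ok))
  expect_true(all(chk$status[chk$domain != "Skin conductance"] == "ok"))
})

test_that("the summary sweep singles out the published significant contrast", {
  tt <- summary_t_tests(reference_summary_tables("both"))
  sig <- tt$feature_name[tt$p_two_tailed < 0.05]
  expect_identical(sig, "ERQ R")
  near <- tt[tt$feature_name == "LF HF ratio FFT", ]
  expect_lt(near$p_two_tailed, 0.1)
  expect_gt(near$p_two_tailed, 0.05)
})

test_that("null calibration: type-I rate sits at the nominal level", {
  set.seed(101)
  n <- 15L
  m <- 4000L  # quick version; the acceptance suite runs 10000
  p <- replicate(m, {
    a <- rnorm(n); b <- rnorm(n)
    t_test_from_summary(mean(a), sd(a), n, mean(b), sd(b), n)$p_two_tailed
  })
  expect_gte(mean(p < 0.05), 0.04 - 0.01)
  expect_lte(mean(p < 0.05), 0.06 + 0.01)
})
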