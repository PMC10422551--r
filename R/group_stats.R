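#' Median split of a flexibility score
#'
#' Dichotomizes a continuous questionnaire score (the Cognitive
#' Flexibility Inventory here) at its sample median: strictly above the
#' median is `"HighFlex"`, strictly below `"LowFlex"`. Scores equal to
#' the median are assigned to alternating groups in subject order
#' (starting with Low), which keeps the two group sizes within one of
#' each other.
#'
#' @param scores Numeric vector, length >= 4.
#' @return Character vector of group labels, same length as `scores`.
#' @export
#' @examples
#' median_split(c(1, 2, 3, 4)) # Low, Low, High, High
median_split <- function(scores) {
  if (length(scores) < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    stop("degenerate split: all scores identical", call. = FALSE)
  }
  med <- stats::median(scores)
  lab <- ifelse(scores > med, "HighFlex",
                ifelse(scores < med, "LowFlex", NA_character_))
  ties <- which(is.na(lab))
  if (length(ties)) {
    n_low <- sum(lab == "LowFlex", na.rm = TRUE)
    n_high <- sum(lab == "HighFlex", na.rm = TRUE)
    for (i in ties) {
      lab[i] <- if (n_low <= n_high) "LowFlex" else "HighFlex"
      if (lab[i] == "LowFlex") n_low <- n_low + 1L else n_high <- n_high + 1L
    }
  }
  lab
}

#' Normality screening: Kolmogorov-Smirnov and Shapiro-Wilk
#'
#' The KS test is the normality variant with mean and SD estimated from
#' the sample (Lilliefors correction, as statistical suites report it);
#' Shapiro-Wilk is the standard test. Results annotate downstream
#' analyses, they never gate them.
#'
#' @param values Numeric vector, n >= 3 (n >= 4 for the KS variant).
#' @return List `ks` and `shapiro`, each with `statistic` and `p_value`;
#'   plus `degenerate = TRUE` when the input has zero variance.
#' @export
normality_tests <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("insufficient data: need n >= 3",
                                call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(ks = list(statistic = NA_real_, p_value = NA_real_),
                shapiro = list(statistic = NA_real_, p_value = NA_real_),
                degenerate = TRUE))
  }
  ks <- nortest::lillie.test(values)
  sw <- stats::shapiro.test(values)
  list(ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
       shapiro = list(statistic = unname(sw$statistic), p_value = sw$p.value),
       degenerate = FALSE)
}

#' Pooled-variance independent t-test from group summaries
#'
#' Student's two-sample t-test computed from per-group mean, SD and n —
#' exactly what published summary tables provide. The pooled SD is
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`,
#' `t = (m_a - m_b) / (s_p sqrt(1/n_a + 1/n_b))` on
#' `df = n_a + n_b - 2`, two-tailed p, and Cohen's d
#' `(m_a - m_b)/s_p`.
#'
#' @param mean_a,sd_a,n_a First-group mean, SD, size (group A is
#'   conventionally High flexibility).
#' @param mean_b,sd_b,n_b Second group.
#' @param feature_name Optional label carried in the result.
#' @return A `group_comparison` list: `feature_name`, `n_high`, `n_low`,
#'   `t_statistic`, `df`, `p_two_tailed`, `cohens_d`, `mean_high`,
#'   `mean_low`, `sd_high`, `sd_low`.
#' @export
#' @examples
#' # Emotion-regulation reappraisal: the one significant group difference
#' t_test_from_summary(32.07, 5.28, 15, 27.4, 4.37, 15)
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                feature_name = NA_character_) {
  if (n_a < 2 || n_b < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd_a < 0 || sd_b < 0 || (sd_a == 0 && sd_b == 0)) {
    stop("SDs must be >= 0 and not both 0", call. = FALSE)
  }
  df <- n_a + n_b - 2
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df)
  t <- (mean_a - mean_b) / (sp * sqrt(1 / n_a + 1 / n_b))
  structure(
    list(feature_name = feature_name, n_high = n_a, n_low = n_b,
         t_statistic = t, df = as.integer(df),
         p_two_tailed = 2 * stats::pt(-abs(t), df),
         cohens_d = (mean_a - mean_b) / sp,
         mean_high = mean_a, mean_low = mean_b,
         sd_high = sd_a, sd_low = sd_b),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3f, p = %.4f, d = %.3f (High %.2f+/-%.2f, Low %.2f+/-%.2f)\n",
              if (is.na(x$feature_name)) "comparison" else x$feature_name,
              x$df, x$t_statistic, x$p_two_tailed, x$cohens_d,
              x$mean_high, x$sd_high, x$mean_low, x$sd_low))
  invisible(x)
}

#' Per-feature group comparisons on a cohort table
#'
#' One pooled-variance t-test per feature column, High vs Low
#' flexibility, using per-group non-missing counts (available-case
#' degrees of freedom per feature). Agrees with
#' [t_test_from_summary()] fed the same per-group moments.
#'
#' @param cohort Cohort `data.frame` with a `group` column
#'   (`"HighFlex"`/`"LowFlex"`) and feature columns.
#' @param features Feature columns to test; default all numeric columns
#'   except `CFI` and identifiers.
#' @param adjust P-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching an uncorrected screen; `"BH"`
#'   available).
#' @return `data.frame` with one row per tested feature: the
#'   `group_comparison` fields plus `p_adjusted`.
#' @export
t_test_table <- function(cohort, features = NULL, adjust = "none") {
  if (!"group" %in% names(cohort)) {
    stop("cohort has no `group` column; run median_split first",
         call. = FALSE)
  }
  if (is.null(features)) {
    num <- vapply(cohort, is.numeric, logical(1))
    features <- setdiff(names(cohort)[num], c("CFI", "subject_id"))
  }
  rows <- list()
  for (f in features) {
    a <- cohort[[f]][cohort$group == "HighFlex"]
    b <- cohort[[f]][cohort$group == "LowFlex"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      warning("feature `", f, "` skipped: fewer than 2 values in a group")
      next
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      warning("feature `", f, "` skipped: zero variance in both groups")
      next
    }
    cmp <- t_test_from_summary(mean(a), stats::sd(a), length(a),
                               mean(b), stats::sd(b), length(b),
                               feature_name = f)
    rows[[f]] <- data.frame(unclass(cmp), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_two_tailed, method = adjust)
  out
}

#' Published cohort group-summary tables
#'
#' The group-level summary statistics (per-group n, mean, SE, SD) of the
#' reference healthy-aging cohort: one table of neuropsychological
#' measures and one of physiological measures, as printed. They
#' parameterize the synthetic cohort sampler and feed the
#' summary-statistic t-tests.
#'
#' Data note: in the printed physiological table the three skin
#' conductance rows carry their SE and SD values transposed (the printed
#' "SE" equals SD*sqrt(n) exactly); [summary_se_consistency()] detects
#' and reports this. The tables here store the values exactly as
#' printed.
#'
#' @param which `"neuropsych"`, `"physio"` or `"both"` (rows combined).
#' @return `data.frame`: `domain`, `measure`, `group`, `n`, `mean`,
#'   `se`, `sd`.
#' @export
reference_summary_tables <- function(which = c("both", "neuropsych",
                                               "physio")) {
  which <- match.arg(which)
  dir <- system.file("extdata", package = "flexiphys")
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, check.names = FALSE,
                                      stringsAsFactors = FALSE)
  np <- rd("neuropsych_summary.tsv")
  ph <- rd("physio_summary.tsv")
  switch(which, neuropsych = np, physio = ph, both = rbind(np, ph))
}

#' Check SE/SD internal consistency of a summary table
#'
#' For each row, tests whether the printed standard error equals
#' `sd / sqrt(n)` within a rounding tolerance; rows failing that but
#' satisfying it with the SE and SD columns exchanged are labelled
#' `"transposed"` (a recognizable typesetting error), all others
#' `"inconsistent"`.
#'
#' @param tab A table as returned by [reference_summary_tables()].
#' @param tol Absolute tolerance on the printed value after rounding the
#'   recomputed one to the printed number of decimals (default 0.01).
#' @return The table with columns `se_expected` and `status`
#'   (`"ok"`/`"transposed"`/`"inconsistent"`).
#' @export
summary_se_consistency <- function(tab, tol = 0.01) {
  exp_se <- tab$sd / sqrt(tab$n)
  round_as_printed <- function(value, printed) {
    d <- vapply(printed, .printed_decimals, integer(1))
    round(value, d)
  }
  direct <- abs(round_as_printed(exp_se, tab$se) - tab$se) <= tol + 1e-9
  swapped <- abs(round_as_printed(tab$se / sqrt(tab$n), tab$sd) - tab$sd) <=
    tol + 1e-9
  tab$se_expected <- exp_se
  tab$status <- ifelse(direct, "ok",
                       ifelse(swapped, "transposed", "inconsistent"))
  tab
}

# number of decimal places a printed value carries (0..8)
.printed_decimals <- function(x) {
  for (d in 0:8) {
    if (abs(x * 10^d - round(x * 10^d)) < 1e-6) return(d)
  }
  8L
}

#' Summary-mode t-tests for every measure of a summary table
#'
#' Runs [t_test_from_summary()] on each measure's High-vs-Low rows.
#'
#' @param tab A table from [reference_summary_tables()].
#' @return `data.frame` of comparisons, one row per measure.
#' @export
summary_t_tests <- function(tab) {
  rows <- list()
  for (m in unique(tab$measure)) {
    sub <- tab[tab$measure == m, ]
    hi <- sub[sub$group == "High Flex", ]
    lo <- sub[sub$group == "Low Flex", ]
    if (nrow(hi) != 1L || nrow(lo) != 1L) next
    cmp <- t_test_from_summary(hi$mean, hi$sd, hi$n, lo$mean, lo$sd, lo$n,
                               feature_name = m)
    rows[[m]] <- data.frame(unclass(cmp), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group specs parameterized by a summary table
#'
#' Turns the per-group (mean, SD) rows of a summary table into
#' [group_spec()] objects for [generate_cohort()], so synthetic cohorts
#' carry the published groups' statistical structure. Group sizes
#' default to the per-measure maximum n in the table.
#'
#' @param tab A table from [reference_summary_tables()].
#' @param n Override subjects per group (default: the table's modal n).
#' @param use_printed_se_sd_for_sc Keep the transposed SC rows as
#'   printed (`FALSE`, default, corrects them before sampling).
#' @return List of two [group_spec()] objects (High, Low).
#' @export
cohort_specs_from_summary <- function(tab, n = NULL,
                                      use_printed_se_sd_for_sc = FALSE) {
  if (!use_printed_se_sd_for_sc) {
    chk <- summary_se_consistency(tab)
    sw <- chk$status == "transposed"
    if (any(sw)) {
      tmp <- tab$se[sw]
      tab$se[sw] <- tab$sd[sw]
      tab$sd[sw] <- tmp
    }
  }
  mk <- function(glabel, spec_label) {
    sub <- tab[tab$group == glabel, ]
    nn <- if (is.null(n)) max(sub$n) else n
    feats <- lapply(seq_len(nrow(sub)), function(i) c(sub$mean[i], sub$sd[i]))
    names(feats) <- sub$measure
    group_spec(spec_label, nn, feats)
  }
  list(mk("High Flex", "HighFlex"), mk("Low Flex", "LowFlex"))
}
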