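#' Generate a cohort with a two-feature threshold rule structure
#'
#' Emulates the discrimination structure found in the reduced
#' physiological model: group membership is decided by two informative
#' features with separation gaps around their generating thresholds —
#' a respiration-type feature (Low flexibility when above its
#' threshold) and, among subjects below it, a heart-rate-type feature
#' (High flexibility when below its threshold) — plus independent
#' Gaussian noise features. Ranking should place the two informative
#' features first and a depth-2 tree should recover the rule, splitting
#' on the respiration-type feature at the root.
#'
#' @param n Number of subjects (default 30).
#' @param thr1 Threshold on the primary (respiration-type) feature.
#' @param thr2 Threshold on the secondary (heart-rate-type) feature.
#' @param gap1,gap2 Half-widths of the value-free gaps around the
#'   thresholds.
#' @param n_noise Number of uninformative standard-normal features.
#' @param seed Integer seed.
#' @return Cohort `data.frame` with features `RMS RSP Rate`, `Max HR`,
#'   `noise1..n_noise`, plus `group` and `CFI`.
#' @export
generate_rule_cohort <- function(n = 30L, thr1 = 35, thr2 = 93,
                                 gap1 = 2, gap2 = 5, n_noise = 8L,
                                 seed = 1L) {
  stopifnot(n >= 10L)
  set.seed(seed)
  # branch sizes mirror the generating rule: 40% above thr1 (all Low),
  # and of the rest, a small minority above thr2 (Low), majority High
  n_a <- round(0.4 * n)               # above thr1 -> Low
  n_rest <- n - n_a
  n_b <- max(1L, round(0.17 * n_rest))  # below thr1, above thr2 -> Low
  n_c <- n_rest - n_b                  # below thr1, below thr2 -> High
  # exceptions (low f1 but Low-flex) sit in the lower part of the low-f1
  # band so the gap around thr1 stays the dominant split on f1
  f1 <- c(stats::runif(n_a, thr1 + gap1, thr1 + gap1 + 6),
          stats::runif(n_b, thr1 - gap1 - 6, thr1 - gap1 - 2),
          stats::runif(n_c, thr1 - gap1 - 6, thr1 - gap1))
  # f2 of the above-thr1 subjects straddles thr2 (half each side, away
  # from the gap) so f2 alone is informative but not separating
  n_a_lo <- n_a %/% 2
  f2 <- c(stats::runif(n_a_lo, thr2 - gap2 - 10, thr2 - gap2),
          stats::runif(n_a - n_a_lo, thr2 + gap2, thr2 + gap2 + 10),
          stats::runif(n_b, thr2 + gap2, thr2 + gap2 + 10),
          stats::runif(n_c, thr2 - gap2 - 10, thr2 - gap2))
  group <- c(rep("LowFlex", n_a), rep("LowFlex", n_b), rep("HighFlex", n_c))
  noise <- matrix(stats::rnorm(n * n_noise), n, n_noise,
                  dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  ord <- sample.int(n)
  out <- data.frame(`RMS RSP Rate` = f1[ord], `Max HR` = f2[ord],
                    check.names = FALSE)
  out <- cbind(out, noise[ord, , drop = FALSE])
  out$group <- group[ord]
  out$CFI <- ifelse(out$group == "HighFlex", 110, 90) +
    stats::runif(n, -5, 5)
  out$subject_id <- sprintf("S%02d", seq_len(n))
  out[, c("subject_id", "group", "CFI", "RMS RSP Rate", "Max HR",
          paste0("noise", seq_len(n_noise)))]
}

#' Generate a well-separated two-cluster cohort
#'
#' Two groups whose feature means sit `separation_sd` pooled SDs apart
#' on every feature — the sanity-check substrate on which any reasonable
#' classifier must reach perfect leave-one-out accuracy.
#'
#' @param n_per_group Subjects per group.
#' @param n_features Number of features.
#' @param separation_sd Group mean separation in pooled-SD units.
#' @param seed Integer seed.
#' @return Cohort `data.frame`.
#' @export
generate_separated_cohort <- function(n_per_group = 15L, n_features = 2L,
                                      separation_sd = 10, seed = 1L) {
  feats <- stats::setNames(
    lapply(seq_len(n_features), function(j) c(0, 1)),
    paste0("f", seq_len(n_features)))
  hi <- lapply(feats, function(ms) c(separation_sd, 1))
  specs <- list(
    group_spec("HighFlex", n_per_group, hi),
    group_spec("LowFlex", n_per_group, feats)
  )
  generate_cohort(specs, seed = seed)
}
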