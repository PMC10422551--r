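test_that("beat detection recovers constant ground-truth intervals", {
  g <- generate_ibi_series(1000, n_beats = 60L, seed = 1L)
  ib <- detect_beats(synthesize_bvp(g, 256))
  expect_true(all(abs(ib$ibis_ms - 1000) <= 1000 / 256))
})

test_that("beat detection recovers an alternating interval pattern", {
  iv <- rep(c(0.9, 1.1), 20)
  g <- structure(list(beat_times = c(0, cumsum(iv)), ibis_ms = iv * 1000,
                      mean_ibi_ms = 1000, modulation_spec = list(),
                      noise_sd_ms = 0), class = "ibi_ground_truth")
  ib <- detect_beats(synthesize_bvp(g, 256))
  d <- ib$ibis_ms
  inner <- d[2:(length(d) - 1)]
  expect_true(all(abs(inner - rep_len(c(1100, 900), length(inner))) < 25) ||
              all(abs(inner - rep_len(c(900, 1100), length(inner))) < 25))
})

test_that("flat input is a detection error, short input a contract error", {
  flat <- sampled_signal(rep(0.5, 64 * 15) + 1e-9 * (1:(64 * 15)), 64, "BVP")
  expect_error(detect_beats(flat), "detection error|flat")
  short <- sampled_signal(sin(2 * pi * (0:200) / 64), 64, "BVP")
  expect_error(detect_beats(short), "10 s")
})

test_that("time-domain indices match hand-evaluated formulas", {
  # degenerate constant series
  td0 <- time_domain_indices(ibi_from_intervals(rep(1000, 10)))
  expect_equal(td0$sdnn_ms, 0)
  expect_equal(td0$rmssd_ms, 0)
  expect_equal(td0$pnn50_percent, 0)
  expect_equal(td0$mean_hr_bpm, 60)
  expect_equal(td0$max_hr_bpm, 60)
  expect_equal(td0$min_hr_bpm, 60)

  # alternating 900/1100: all successive diffs are 200 ms
  td <- time_domain_indices(ibi_from_intervals(c(900, 1100, 900, 1100)))
  expect_equal(td$rmssd_ms, 200)
  expect_equal(td$nn50_count, 3L)
  expect_equal(td$pnn50_percent, 100)
  expect_equal(td$sdnn_ms, sqrt(4 * 100^2 / 3))

  # strictly-greater-than-50ms rule
  td40 <- time_domain_indices(ibi_from_intervals(c(1000, 1040, 1000)))
  expect_identical(td40$nn50_count, 0L)

  # mean HR / mean RR identity
  expect_equal(td$mean_hr_bpm, 60000 / td$mean_rr_ms)
})

test_that("time-domain indices ignore a constant beat-time offset", {
  iv <- c(800, 950, 1010, 870, 990, 920)
  a <- time_domain_indices(ibi_from_intervals(iv))
  b <- time_domain_indices(ibi_from_intervals(iv, t0 = 1234.5))
  expect_equal(a, b)
})

test_that("Max/Min HR come from the N-beat moving average", {
  iv <- c(1000, 1000, 500, 1000, 1000)
  td1 <- time_domain_indices(ibi_from_intervals(iv), ma_beats = 1L)
  expect_equal(td1$max_hr_bpm, 120)
  td3 <- time_domain_indices(ibi_from_intervals(iv), ma_beats = 3L)
  expect_equal(td3$max_hr_bpm, 60000 / mean(c(1000, 500, 1000)))
})

test_that("a pure LF tone lands its power in the LF band (Parseval)", {
  g <- generate_ibi_series(1000, list(list(freq_hz = 0.1, amp_ms = 50)),
                           n_beats = 300L, seed = 3L)
  fd <- frequency_domain_indices(ibi_series(g$beat_times))
  expect_equal(fd$lf_power_ms2, 50^2 / 2, tolerance = 0.15)
  expect_lt(fd$hf_power_ms2 / fd$lf_power_ms2, 0.05)
  expect_equal(fd$peak_frequency_hz, 0.1, tolerance = 0.2)

  g25 <- generate_ibi_series(1000, list(list(freq_hz = 0.25, amp_ms = 50)),
                             n_beats = 300L, seed = 3L)
  fd25 <- frequency_domain_indices(ibi_series(g25$beat_times))
  expect_equal(fd25$hf_power_ms2, 50^2 / 2, tolerance = 0.15)
  expect_lt(fd25$lf_power_ms2 / fd25$hf_power_ms2, 0.05)
})

test_that("constant intervals give essentially zero spectral power", {
  ib <- ibi_from_intervals(rep(1000, 120))
  fd <- frequency_domain_indices(ib)
  total <- fd$vlf_power_ms2 + fd$lf_power_ms2 + fd$hf_power_ms2
  expect_lt(total, 1e-6 * 1000^2)
})

test_that("band powers approximate the tachogram variance", {
  g <- generate_ibi_series(1000,
                           list(list(freq_hz = 0.09, amp_ms = 40),
                                list(freq_hz = 0.27, amp_ms = 25)),
                           n_beats = 360L, noise_sd_ms = 0, seed = 9L)
  fd <- frequency_domain_indices(ibi_series(g$beat_times))
  total <- fd$vlf_power_ms2 + fd$lf_power_ms2 + fd$hf_power_ms2
  expect_equal(total, 40^2 / 2 + 25^2 / 2, tolerance = 0.2)
})

test_that("too-short recordings are refused with the required duration", {
  ib <- ibi_from_intervals(rep(1000, 30))
  expect_error(frequency_domain_indices(ib), ">= 60")
})

test_that("Poincare indices: identity with RMSSD and axis geometry", {
  # degenerate
  pc0 <- poincare_indices(ibi_from_intervals(rep(1000, 10)))
  expect_equal(pc0$sd1_ms, 0)
  expect_equal(pc0$sd2_ms, 0)
  expect_true(is.na(pc0$sd2_sd1_ratio))

  # SD1-RMSSD identity at floating precision on an arbitrary series
  set.seed(4)
  iv <- 1000 + cumsum(rnorm(100, 0, 20))
  ib <- ibi_from_intervals(iv)
  td <- time_domain_indices(ib)
  pc <- poincare_indices(ib)
  expect_equal(pc$sd1_ms, td$rmssd_ms / sqrt(2), tolerance = 1e-9)

  # independent brute-force projections for a drifting series
  drift <- seq(1000, 1100, by = 2)
  pcd <- poincare_indices(ibi_from_intervals(drift))
  x <- drift[-length(drift)]; y <- drift[-1]
  expect_equal(pcd$sd1_ms, sqrt(mean((y - x)^2 / 2)), tolerance = 1e-12)
  expect_equal(pcd$sd2_ms, sd((x + y) / sqrt(2)), tolerance = 1e-12)
  expect_gt(pcd$sd2_sd1_ratio, 10)
})

test_that("full pipeline recovers ground-truth HRV from clean BVP", {
  fix <- clean_bvp_fixture()
  ib <- detect_beats(fix$bvp)
  truth_td <- time_domain_indices(ibi_series(fix$truth$beat_times))
  td <- time_domain_indices(ib)
  expect_lt(abs(td$mean_rr_ms - truth_td$mean_rr_ms), 2)
  expect_lt(abs(td$sdnn_ms / truth_td$sdnn_ms - 1), 0.05)
  expect_lt(abs(td$rmssd_ms / truth_td$rmssd_ms - 1), 0.05)
})

test_that("cardiac feature vector carries the cohort-table names", {
  fix <- clean_bvp_fixture()
  fv <- cardiac_features(fix$bvp)
  expect_true(all(c("RMSSD", "SDNN", "Max HR", "NN50", "VLF pow FFT",
                    "LF pow FFT", "HF pow FFT", "LF HF ratio FFT",
                    "SD1", "SD2", "SD2 SD1 ratio") %in% names(fv)))
  expect_equal(unname(fv["SD1"]), unname(fv["RMSSD"]) / sqrt(2),
               tolerance = 1e-9)
})
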