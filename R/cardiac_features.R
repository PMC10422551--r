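#' Construct an inter-beat-interval series
#'
#' Beat times (s) with their successive intervals (ms) and optional
#' per-beat pulse amplitudes; the substrate of every HRV index.
#'
#' @param beat_times Strictly increasing beat times, seconds.
#' @param amplitudes Optional per-beat amplitudes (a.u.).
#' @return An `ibi_series` with `beat_times`, `ibis_ms`, `amplitudes`.
#' @export
ibi_series <- function(beat_times, amplitudes = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L || any(diff(beat_times) <= 0)) {
    stop("beat_times must be strictly increasing, length >= 2", call. = FALSE)
  }
  if (!is.null(amplitudes) && length(amplitudes) != length(beat_times)) {
    stop("one amplitude per beat required", call. = FALSE)
  }
  structure(list(beat_times = beat_times,
                 ibis_ms = diff(beat_times) * 1000,
                 amplitudes = amplitudes),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats over %.1f s, mean IBI %.1f ms\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$ibis_ms)))
  invisible(x)
}

#' Beat-detection configuration
#'
#' @param min_ibi_ms,max_ibi_ms Physiological plausibility window for
#'   intervals; detections implying intervals outside it are dropped and
#'   the series re-spliced (when `resplice = TRUE`) or kept flagged.
#' @param refractory_s Minimum peak-to-peak distance during detection.
#' @param min_prominence Minimum peak height, as a fraction of the
#'   signal's 5th-95th percentile span.
#' @param resplice Drop implausible beats and recompute intervals from
#'   the surviving beat times.
#' @return A list of settings for [detect_beats()].
#' @export
beat_config <- function(min_ibi_ms = 300, max_ibi_ms = 2000,
                        refractory_s = 0.3, min_prominence = 0.3,
                        resplice = TRUE) {
  list(min_ibi_ms = min_ibi_ms, max_ibi_ms = max_ibi_ms,
       refractory_s = refractory_s, min_prominence = min_prominence,
       resplice = resplice)
}

#' Detect heartbeats in a blood-volume-pulse signal
#'
#' Each pulse maximum marks one beat. Candidate maxima must clear an
#' amplitude threshold and a refractory period; peak times are refined to
#' sub-sample precision by parabolic interpolation through the peak and
#' its neighbours. Per-beat amplitude is peak minus the preceding trough.
#'
#' @param bvp A [sampled_signal()] (any channel; BVP expected), duration
#'   >= 10 s, rate >= 32 Hz.
#' @param config A [beat_config()].
#' @return An [ibi_series()].
#' @export
detect_beats <- function(bvp, config = beat_config()) {
  stopifnot(inherits(bvp, "sampled_signal"))
  if (duration(bvp) < 10) stop("need at least 10 s of signal", call. = FALSE)
  if (bvp$sampling_rate_hz < 32) stop("need sampling rate >= 32 Hz",
                                      call. = FALSE)
  x <- bvp$samples
  fs <- bvp$sampling_rate_hz
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  span <- qs[2L] - qs[1L]
  if (span <= 0) stop("detection error: flat signal, no beats found",
                      call. = FALSE)
  thr <- qs[1L] + config$min_prominence * span
  pk <- pracma::findpeaks(x, minpeakheight = thr,
                          minpeakdistance = max(1L, round(config$refractory_s * fs)))
  if (is.null(pk) || nrow(pk) < 3L) {
    stop("detection error: fewer than 3 beats detected", call. = FALSE)
  }
  idx <- sort(pk[, 2L])
  # sub-sample refinement: vertex of the parabola through (i-1, i, i+1)
  tt <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (i > 1L && i < length(x)) {
      a <- x[i - 1L]; b <- x[i]; c <- x[i + 1L]
      den <- a - 2 * b + c
      delta <- if (den < 0) 0.5 * (a - c) / den else 0
      delta <- max(-0.5, min(0.5, delta))
    } else delta <- 0
    tt[j] <- (i - 1L + delta) / fs
  }
  # amplitude: peak minus the minimum since the previous peak
  amp <- numeric(length(idx))
  prev <- 1L
  for (j in seq_along(idx)) {
    amp[j] <- x[idx[j]] - min(x[prev:idx[j]])
    prev <- idx[j]
  }
  ib <- diff(tt) * 1000
  bad <- which(ib < config$min_ibi_ms | ib > config$max_ibi_ms)
  if (length(bad) && config$resplice) {
    # drop the later beat of each implausible interval, then recompute
    keep <- setdiff(seq_along(tt), bad + 1L)
    tt <- tt[keep]; amp <- amp[keep]
  }
  if (length(tt) < 3L) {
    stop("detection error: fewer than 3 plausible beats", call. = FALSE)
  }
  ibi_series(tt, amp)
}

#' Time-domain heart-rate-variability indices
#'
#' SDNN is the sample SD (n-1) of the intervals; RMSSD the root mean
#' square of successive differences; NN50/pNN50 the count/percentage of
#' successive differences exceeding 50 ms; Max and Min HR the extrema of
#' 60000 over an `ma_beats`-beat moving average of the intervals.
#'
#' @param ibi An [ibi_series()] with >= 3 intervals.
#' @param ma_beats Window, in beats, of the moving average behind
#'   Max/Min HR (default 5).
#' @return List: `mean_rr_ms`, `mean_hr_bpm`, `sdnn_ms`, `rmssd_ms`,
#'   `nn50_count`, `pnn50_percent`, `max_hr_bpm`, `min_hr_bpm`.
#' @export
time_domain_indices <- function(ibi, ma_beats = 5L) {
  rr <- ibi$ibis_ms
  if (length(rr) < 3L) stop("need at least 3 intervals", call. = FALSE)
  d <- diff(rr)
  ma_beats <- min(as.integer(ma_beats), length(rr))
  ma <- stats::filter(rr, rep(1 / ma_beats, ma_beats), sides = 2)
  ma <- ma[!is.na(ma)]
  hr_ma <- 60000 / ma
  list(
    mean_rr_ms = mean(rr),
    mean_hr_bpm = 60000 / mean(rr),
    sdnn_ms = stats::sd(rr),
    rmssd_ms = sqrt(mean(d^2)),
    nn50_count = sum(abs(d) > 50),
    pnn50_percent = 100 * sum(abs(d) > 50) / length(d),
    max_hr_bpm = max(hr_ma),
    min_hr_bpm = min(hr_ma)
  )
}

#' Spectral band edges for heart-rate-variability analysis
#'
#' Very-low, low and high frequency bands of the interval tachogram.
#' The high band runs to 0.5 Hz.
#' @param vlf,lf,hf Length-2 numeric band edges in Hz.
#' @return List of bands, checked contiguous, non-overlapping, ordered.
#' @export
frequency_bands <- function(vlf = c(0, 0.04), lf = c(0.04, 0.15),
                            hf = c(0.15, 0.5)) {
  b <- list(vlf = vlf, lf = lf, hf = hf)
  edges <- unlist(b)
  if (any(diff(edges) < 0) || vlf[2] != lf[1] || lf[2] != hf[1]) {
    stop("bands must be contiguous, non-overlapping and ordered",
         call. = FALSE)
  }
  b
}

#' Spectral-analysis configuration for the tachogram
#'
#' @param interp_rate_hz Evenly sampled tachogram rate (default 4 Hz).
#' @param interp_method `"cubic"` (spline) or `"linear"`.
#' @param segment_s Welch segment length in seconds (default 64).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param min_span_s Minimum recording span required.
#' @param vlf_reliable_span_s Span below which the very-low-frequency
#'   estimate is flagged unreliable.
#' @return Settings list for [frequency_domain_indices()].
#' @export
spectral_config <- function(interp_rate_hz = 4, interp_method = "cubic",
                            segment_s = 64, overlap = 0.5,
                            min_span_s = 60, vlf_reliable_span_s = 300) {
  list(interp_rate_hz = interp_rate_hz, interp_method = interp_method,
       segment_s = segment_s, overlap = overlap, min_span_s = min_span_s,
       vlf_reliable_span_s = vlf_reliable_span_s)
}

#' Welch power spectral density
#'
#' Hann-windowed, overlapping segments, per-segment mean removal;
#' one-sided density so that `sum(psd) * df` equals the signal variance
#' (up to leakage) for a stationary input.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples.
#' @param overlap Fractional overlap between segments.
#' @return List `freq` (Hz) and `psd` (input-units^2 per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 256L), overlap = 0.5) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  u <- sum(w^2)  # window power normalisation
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # fold negative frequencies into the one-sided density
  interior <- 2:(nfreq - if (nperseg %% 2 == 0) 1L else 0L)
  psd[interior] <- 2 * psd[interior]
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = psd)
}

#' Frequency-domain heart-rate-variability indices
#'
#' The interval series is interpolated onto an evenly sampled tachogram
#' (cubic spline at 4 Hz by default), mean-removed, and its power
#' spectral density estimated by Welch's method. Band powers are the
#' integral of the density over the very-low (<0.04 Hz), low
#' (0.04-0.15 Hz) and high (0.15-0.5 Hz) frequency bands, in ms^2; the
#' low/high ratio is the classical sympathovagal balance index. The
#' spectral peak inside the low+high analysis band is reported both as
#' its frequency and as the density magnitude at that frequency.
#'
#' @param ibi An [ibi_series()] spanning >= `min_span_s` (default 60 s).
#' @param bands A [frequency_bands()].
#' @param config A [spectral_config()].
#' @return List: `vlf_power_ms2`, `lf_power_ms2`, `hf_power_ms2`,
#'   `lf_hf_ratio`, `peak_frequency_hz`, `peak_magnitude`,
#'   `vlf_reliable`, plus the `freq`/`psd` arrays.
#' @export
frequency_domain_indices <- function(ibi, bands = frequency_bands(),
                                     config = spectral_config()) {
  span <- diff(range(ibi$beat_times))
  if (span < config$min_span_s) {
    stop("insufficient data: recording spans ", round(span, 1),
         " s, need >= ", config$min_span_s, " s", call. = FALSE)
  }
  fs <- config$interp_rate_hz
  tg_t <- seq(ibi$beat_times[2L], ibi$beat_times[length(ibi$beat_times)],
              by = 1 / fs)
  # tachogram: interval value attributed to the time of the closing beat
  tg <- if (identical(config$interp_method, "cubic")) {
    stats::spline(ibi$beat_times[-1L], ibi$ibis_ms, xout = tg_t)$y
  } else {
    stats::approx(ibi$beat_times[-1L], ibi$ibis_ms, xout = tg_t)$y
  }
  tg <- tg - mean(tg)
  nseg <- min(length(tg), round(config$segment_s * fs))
  sp <- welch_psd(tg, fs, nperseg = nseg, overlap = config$overlap)
  df <- sp$freq[2L] - sp$freq[1L]
  band_power <- function(b) sum(sp$psd[sp$freq >= b[1L] & sp$freq < b[2L]]) * df
  vlf <- band_power(bands$vlf)
  lf <- band_power(bands$lf)
  hf <- band_power(c(bands$hf[1L], bands$hf[2L] + df / 2))  # closed upper edge
  in_band <- sp$freq >= bands$lf[1L] & sp$freq <= bands$hf[2L]
  pk <- which.max(sp$psd * in_band)
  list(
    vlf_power_ms2 = vlf, lf_power_ms2 = lf, hf_power_ms2 = hf,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
    peak_frequency_hz = sp$freq[pk],
    peak_magnitude = sp$psd[pk],
    vlf_reliable = span >= config$vlf_reliable_span_s,
    freq = sp$freq, psd = sp$psd
  )
}

#' Poincare-plot indices
#'
#' With lagged pairs `(x_k, y_k) = (IBI_k, IBI_{k+1})`, SD1 is the
#' dispersion of the points perpendicular to the identity line and SD2
#' the dispersion along it. SD1 is computed as the root-mean-square of
#' `(y - x)/sqrt(2)` (uncentred, matching the RMSSD convention), so the
#' identity `SD1 = RMSSD / sqrt(2)` holds exactly; SD2 is the sample SD
#' of `(y + x)/sqrt(2)`. The ratio follows the convention with values
#' above 1 for typical interval series, SD2/SD1; the reciprocal is also
#' returned.
#'
#' @param ibi An [ibi_series()] with >= 3 intervals.
#' @return List: `sd1_ms`, `sd2_ms`, `sd2_sd1_ratio`, `sd1_sd2_ratio`
#'   (ratios `NA` when SD1 is 0).
#' @export
poincare_indices <- function(ibi) {
  rr <- ibi$ibis_ms
  if (length(rr) < 3L) stop("need at least 3 intervals", call. = FALSE)
  x <- rr[-length(rr)]
  y <- rr[-1L]
  sd1 <- sqrt(mean((y - x)^2 / 2))
  sd2 <- stats::sd((y + x) / sqrt(2))
  list(
    sd1_ms = sd1, sd2_ms = sd2,
    sd2_sd1_ratio = if (sd1 > 0) sd2 / sd1 else NA_real_,
    sd1_sd2_ratio = if (sd2 > 0) sd1 / sd2 else NA_real_
  )
}

#' All cardiac features of one recording, named as in the cohort tables
#'
#' Convenience wrapper running beat detection and the three HRV domains,
#' returning one named feature vector per subject with the feature names
#' used throughout the cohort tables.
#'
#' @param bvp A [sampled_signal()] BVP recording.
#' @param ma_beats Moving-average window for Max/Min HR.
#' @param bands,spectral,beats Stage configurations.
#' @return Named numeric vector of cardiac features.
#' @export
cardiac_features <- function(bvp, ma_beats = 5L, bands = frequency_bands(),
                             spectral = spectral_config(),
                             beats = beat_config()) {
  ib <- detect_beats(bvp, beats)
  td <- time_domain_indices(ib, ma_beats)
  fd <- frequency_domain_indices(ib, bands, spectral)
  pc <- poincare_indices(ib)
  c("HR mean" = td$mean_hr_bpm, "RR mean" = td$mean_rr_ms,
    "RMSSD" = td$rmssd_ms, "SDNN" = td$sdnn_ms,
    "Max HR" = td$max_hr_bpm, "Min HR" = td$min_hr_bpm,
    "NN50" = td$nn50_count, "pNN50" = td$pnn50_percent,
    "VLF pow FFT" = fd$vlf_power_ms2, "LF pow FFT" = fd$lf_power_ms2,
    "HF pow FFT" = fd$hf_power_ms2, "LF HF ratio FFT" = fd$lf_hf_ratio,
    "RR peak frequency" = fd$peak_frequency_hz,
    "RR peak magnitude" = fd$peak_magnitude,
    "SD1" = pc$sd1_ms, "SD2" = pc$sd2_ms,
    "SD2 SD1 ratio" = pc$sd2_sd1_ratio)
}
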