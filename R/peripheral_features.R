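#' Respiration-analysis configuration
#'
#' @param band_hz Zero-phase band-pass edges applied before peak
#'   detection (default 0.05-1.0 Hz, i.e. 3-60 breaths/min).
#' @param refractory_s Minimum breath-to-breath peak distance.
#' @param filter_order Butterworth order.
#' @return Settings list for [respiration_indices()].
#' @export
respiration_config <- function(band_hz = c(0.05, 1.0), refractory_s = 1,
                               filter_order = 2) {
  list(band_hz = band_hz, refractory_s = refractory_s,
       filter_order = filter_order)
}

#' Respiration-rate indices
#'
#' The signal is band-pass filtered (zero phase) to a smooth sinusoid,
#' breath maxima are detected with a refractory period, each
#' maximum-to-maximum time is one respiration period, and the
#' instantaneous rate is 60/period breaths per minute. Mean, sample SD
#' and RMS are taken over the per-breath rate series; rates depend on
#' peak times only, so the indices are invariant to amplitude scaling.
#'
#' @param rsp A [sampled_signal()], duration >= 30 s.
#' @param config A [respiration_config()].
#' @return List: `mean_rate_bpm`, `sd_rate_bpm`, `rms_rate_bpm`,
#'   `n_breaths`, `rate_series_bpm`.
#' @export
respiration_indices <- function(rsp, config = respiration_config()) {
  stopifnot(inherits(rsp, "sampled_signal"))
  if (duration(rsp) < 30) stop("need at least 30 s of respiration",
                               call. = FALSE)
  fs <- rsp$sampling_rate_hz
  ny <- fs / 2
  bf <- signal::butter(config$filter_order,
                       pmin(config$band_hz / ny, 0.99), type = "pass")
  xf <- signal::filtfilt(bf, rsp$samples - mean(rsp$samples))
  pk <- pracma::findpeaks(xf, minpeakheight = 0.2 * stats::sd(xf),
                          minpeakdistance = max(1L, round(config$refractory_s * fs)))
  if (is.null(pk) || nrow(pk) < 3L) {
    stop("insufficient data: fewer than 3 breath peaks", call. = FALSE)
  }
  idx <- sort(pk[, 2L])
  # sub-sample peak times (parabolic vertex), as for beats
  tt <- vapply(idx, function(i) {
    if (i > 1L && i < length(xf)) {
      den <- xf[i - 1L] - 2 * xf[i] + xf[i + 1L]
      d <- if (den < 0) 0.5 * (xf[i - 1L] - xf[i + 1L]) / den else 0
      (i - 1L + max(-0.5, min(0.5, d))) / fs
    } else (i - 1L) / fs
  }, numeric(1))
  periods <- diff(tt)
  rates <- 60 / periods
  list(mean_rate_bpm = mean(rates),
       sd_rate_bpm = stats::sd(rates),
       rms_rate_bpm = sqrt(mean(rates^2)),
       n_breaths = length(rates),
       rate_series_bpm = rates)
}

#' Moving-window RMS envelope of an EMG signal
#'
#' Rectification of the raw electromyogram into an amplitude envelope:
#' the square root of a centred moving average of the squared,
#' zero-meaned signal. Output stays on the input grid; edge windows are
#' truncated.
#'
#' @param emg A [sampled_signal()].
#' @param window_s Window length in seconds (positive, shorter than the
#'   recording).
#' @return A [sampled_signal()] holding the envelope.
#' @export
emg_envelope <- function(emg, window_s = 0.1) {
  stopifnot(inherits(emg, "sampled_signal"))
  if (window_s <= 0 || window_s >= duration(emg)) {
    stop("window_s must be positive and shorter than the recording",
         call. = FALSE)
  }
  x <- emg$samples - mean(emg$samples)
  n <- length(x)
  w <- max(1L, round(window_s * emg$sampling_rate_hz))
  half <- w %/% 2
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  env <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  out <- emg
  out$samples <- env
  out
}

#' EMG channel-ratio indices (corrugator vs zygomatic)
#'
#' Each channel is converted to its RMS envelope; the sample-wise ratio
#' series `env2/env1` and `env1/env2` are formed with an epsilon floor on
#' the denominator (a fraction of that channel's median envelope) to
#' avoid division blow-ups during rest; mean, sample SD and RMS of each
#' ratio series are reported.
#'
#' @param emg1 Corrugator channel ([sampled_signal()]).
#' @param emg2 Zygomatic channel, same rate and duration (within one
#'   sample).
#' @param window_s Envelope window, seconds.
#' @param eps_frac Denominator floor as a fraction of the channel median
#'   envelope.
#' @return List: `mean_ratio_12`, `mean_ratio_21`, `sd_ratio_12`,
#'   `sd_ratio_21`, `rms_ratio_12`, `rms_ratio_21`.
#' @export
emg_ratio_indices <- function(emg1, emg2, window_s = 0.1, eps_frac = 0.01) {
  stopifnot(inherits(emg1, "sampled_signal"), inherits(emg2, "sampled_signal"))
  if (!isTRUE(all.equal(emg1$sampling_rate_hz, emg2$sampling_rate_hz)) ||
      abs(length(emg1$samples) - length(emg2$samples)) > 1L) {
    stop("alignment error: channels differ in rate or duration", call. = FALSE)
  }
  n <- min(length(emg1$samples), length(emg2$samples))
  e1 <- emg_envelope(emg1, window_s)$samples[seq_len(n)]
  e2 <- emg_envelope(emg2, window_s)$samples[seq_len(n)]
  f1 <- pmax(e1, eps_frac * stats::median(e1))
  f2 <- pmax(e2, eps_frac * stats::median(e2))
  r12 <- e1 / f2   # EMG1/EMG2
  r21 <- e2 / f1   # EMG2/EMG1
  list(mean_ratio_12 = mean(r12), mean_ratio_21 = mean(r21),
       sd_ratio_12 = stats::sd(r12), sd_ratio_21 = stats::sd(r21),
       rms_ratio_12 = sqrt(mean(r12^2)), rms_ratio_21 = sqrt(mean(r21^2)),
       ratio_series_12 = r12, ratio_series_21 = r21)
}

#' Skin-conductance configuration
#'
#' @param target_rate_hz Analysis rate; conductance is slow enough that
#'   32 Hz carries it without distortion.
#' @param median_window_s Median-filter window for artifact reduction.
#' @param mad_k Samples further than `mad_k` robust SDs from the rolling
#'   median baseline are clipped to the baseline.
#' @return Settings list for [sc_indices()].
#' @export
sc_config <- function(target_rate_hz = 32, median_window_s = 0.5, mad_k = 5) {
  list(target_rate_hz = target_rate_hz, median_window_s = median_window_s,
       mad_k = mad_k)
}

#' Skin-conductance indices
#'
#' The conductance trace is resampled to 32 Hz, artifact-reduced by a
#' running median plus clipping of samples far from the rolling baseline
#' (in robust-SD units), and summarised as mean, sample SD and RMS in
#' microsiemens.
#'
#' @param sc A [sampled_signal()] in microsiemens, duration >= 10 s.
#' @param config An [sc_config()].
#' @return List: `mean_sc_us`, `sd_sc_us`, `rms_sc_us`, and the
#'   artifact-reduced series `series_us`.
#' @export
sc_indices <- function(sc, config = sc_config()) {
  stopifnot(inherits(sc, "sampled_signal"))
  if (duration(sc) < 10) stop("need at least 10 s of conductance",
                              call. = FALSE)
  if (all(sc$samples < 0)) {
    stop("units error: conductance is negative throughout", call. = FALSE)
  }
  if (!isTRUE(all.equal(sc$sampling_rate_hz, config$target_rate_hz))) {
    sc <- resample_signal(sc, config$target_rate_hz)
  }
  x <- sc$samples
  k <- max(3L, round(config$median_window_s * config$target_rate_hz))
  if (k %% 2 == 0) k <- k + 1L
  base <- stats::runmed(x, k)
  resid <- x - base
  s <- stats::mad(resid)
  if (s > 0) {
    clipped <- abs(resid) > config$mad_k * s
    x[clipped] <- base[clipped]
  }
  y <- stats::runmed(x, k)
  list(mean_sc_us = mean(y), sd_sc_us = stats::sd(y),
       rms_sc_us = sqrt(mean(y^2)), series_us = y)
}

#' Peripheral features of one session, named as in the cohort tables
#'
#' @param rsp,emg1,emg2,sc [sampled_signal()] recordings (any subset;
#'   `NULL` entries are skipped).
#' @param window_s EMG envelope window.
#' @return Named numeric vector of respiration, EMG-ratio and
#'   skin-conductance features.
#' @export
peripheral_features <- function(rsp = NULL, emg1 = NULL, emg2 = NULL,
                                sc = NULL, window_s = 0.1) {
  out <- numeric(0)
  if (!is.null(rsp)) {
    r <- respiration_indices(rsp)
    out <- c(out, "Mean RSP Rate" = r$mean_rate_bpm,
             "StD RSP Rate" = r$sd_rate_bpm,
             "RMS RSP Rate" = r$rms_rate_bpm)
  }
  if (!is.null(emg1) && !is.null(emg2)) {
    e <- emg_ratio_indices(emg1, emg2, window_s)
    out <- c(out, "mean EMG1/EMG2" = e$mean_ratio_12,
             "mean EMG2/EMG1" = e$mean_ratio_21,
             "StD EMG1/EMG2" = e$sd_ratio_12,
             "StD EMG2/EMG1" = e$sd_ratio_21,
             "RMS EMG1/EMG2" = e$rms_ratio_12,
             "RMS EMG2/EMG1" = e$rms_ratio_21)
  }
  if (!is.null(sc)) {
    s <- sc_indices(sc)
    out <- c(out, "Mean SC" = s$mean_sc_us, "StD SC" = s$sd_sc_us,
             "RMS SC" = s$rms_sc_us)
  }
  out
}
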