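#' Generate an inter-beat-interval series with known ground truth
#'
#' Beat-to-beat intervals are a mean plus a sum of sinusoidal modulations
#' plus white Gaussian noise:
#' `IBI_k = mean + sum_j A_j sin(2 pi f_j t_k + phi_j) + eps_k`,
#' with beat times accumulated from the intervals themselves. Sinusoidal
#' modulation at a chosen frequency places variability into a chosen
#' spectral band of the tachogram, giving every heart-rate-variability
#' index a known target.
#'
#' @param mean_ibi_ms Mean interval in ms (positive).
#' @param modulation_spec List of modulations, each
#'   `list(freq_hz=, amp_ms=, phase_rad=)` (phase defaults to 0).
#' @param n_beats Number of beats to generate.
#' @param noise_sd_ms SD of additive white noise, ms.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return An `ibi_ground_truth` object: `beat_times` (s), `ibis_ms`,
#'   `mean_ibi_ms`, `modulation_spec`, `noise_sd_ms`.
#' @export
#' @examples
#' g <- generate_ibi_series(1000, list(list(freq_hz = 0.1, amp_ms = 50)),
#'                          n_beats = 300, seed = 1)
#' sd(g$ibis_ms) # close to 50 / sqrt(2)
generate_ibi_series <- function(mean_ibi_ms, modulation_spec = list(),
                                n_beats = 300L, noise_sd_ms = 0, seed = 1L) {
  stopifnot(mean_ibi_ms > 0, n_beats >= 2L, noise_sd_ms >= 0)
  set.seed(seed)
  # intervals depend on their own start times; accumulate sequentially
  ibis <- numeric(n_beats - 1L)
  t <- 0
  eps <- if (noise_sd_ms > 0) stats::rnorm(n_beats - 1L, 0, noise_sd_ms) else
    numeric(n_beats - 1L)
  for (k in seq_len(n_beats - 1L)) {
    mod <- 0
    for (m in modulation_spec) {
      ph <- if (is.null(m$phase_rad)) 0 else m$phase_rad
      mod <- mod + m$amp_ms * sin(2 * pi * m$freq_hz * t + ph)
    }
    ibis[k] <- mean_ibi_ms + mod + eps[k]
    # sub-millisecond intervals mean the modulation has driven the series
    # into (or asymptotically toward) zero: refuse rather than emit them
    if (ibis[k] < 1) {
      stop("generated IBI <= 0 (or vanishing) at beat ", k,
           "; reduce modulation amplitudes or noise SD", call. = FALSE)
    }
    t <- t + ibis[k] / 1000
  }
  structure(
    list(beat_times = c(0, cumsum(ibis) / 1000), ibis_ms = ibis,
         mean_ibi_ms = mean_ibi_ms, modulation_spec = modulation_spec,
         noise_sd_ms = noise_sd_ms),
    class = "ibi_ground_truth"
  )
}

# one stereotyped pulse: fast rise, slow decay (gamma-like), unit peak at
# tau = 0; x^(k-1) e^-x peaks at x = k-1, so shift/scale puts that at tau = 0
.pulse_template <- function(tau, width_s) {
  shape <- 3
  u <- (shape - 1) + shape * tau / width_s
  ifelse(u > 0,
         u^(shape - 1) * exp(-(u - (shape - 1))) / (shape - 1)^(shape - 1),
         0)
}

#' Synthesize a blood-volume-pulse waveform from beat times
#'
#' Places one stereotyped pulse (fast rise, slow decay; width 0.3 of the
#' local interval) per beat, with its maximum at the beat time. The
#' waveform exists purely to carry known beat positions into the
#' beat-detection stage.
#'
#' @param ibi An `ibi_ground_truth` from [generate_ibi_series()].
#' @param sampling_rate_hz Output rate, >= 32 Hz.
#' @param amplitudes Per-beat pulse amplitude; recycled.
#' @return A [sampled_signal()] with channel `"BVP"`.
#' @export
synthesize_bvp <- function(ibi, sampling_rate_hz = 256, amplitudes = 1) {
  stopifnot(inherits(ibi, "ibi_ground_truth"), sampling_rate_hz >= 32)
  bt <- ibi$beat_times
  amplitudes <- rep_len(amplitudes, length(bt))
  total <- bt[length(bt)] + 1
  n <- ceiling(total * sampling_rate_hz)
  tt <- (seq_len(n) - 1) / sampling_rate_hz
  x <- numeric(n)
  local_ibi <- c(ibi$ibis_ms, ibi$ibis_ms[length(ibi$ibis_ms)]) / 1000
  for (k in seq_along(bt)) {
    w <- 0.3 * local_ibi[k]
    lo <- max(1L, floor((bt[k] - 2 * w) * sampling_rate_hz) + 1L)
    hi <- min(n, ceiling((bt[k] + 6 * w) * sampling_rate_hz) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] + amplitudes[k] * .pulse_template(tt[idx] - bt[k], w)
  }
  sampled_signal(x, sampling_rate_hz, "BVP", "a.u.")
}

#' Synthesize a respiration signal with a prescribed rate profile
#'
#' A phase-continuous sinusoid whose instantaneous frequency follows the
#' requested breathing-rate profile (breaths/min), emulating the smooth
#' filtered respiration trace from which breath-to-breath periods are
#' read.
#'
#' @param rate_profile Either a single rate (breaths/min) or a function
#'   of time (s) returning the rate.
#' @param duration_s Length of the signal in seconds.
#' @param sampling_rate_hz Sampling rate.
#' @return A [sampled_signal()] with channel `"RSP"`.
#' @export
synthesize_respiration <- function(rate_profile, duration_s,
                                   sampling_rate_hz = 256) {
  n <- ceiling(duration_s * sampling_rate_hz)
  tt <- (seq_len(n) - 1) / sampling_rate_hz
  rate <- if (is.function(rate_profile)) rate_profile(tt) else
    rep_len(rate_profile, n)
  if (any(rate <= 0)) stop("rate_profile must be positive", call. = FALSE)
  freq_hz <- rate / 60
  phase <- 2 * pi * cumsum(freq_hz) / sampling_rate_hz
  # sin(phase - pi/2) starts at a trough so the first maximum is interior
  sampled_signal(sin(phase - pi / 2), sampling_rate_hz, "RSP", "a.u.")
}

#' Synthesize a raw facial-EMG-like signal
#'
#' Zero-mean broadband Gaussian noise multiplied by a burst envelope;
#' the envelope is the ground truth the RMS-envelope stage must recover.
#'
#' @param burst_envelope Single value, vector (recycled/interpolated to
#'   the signal grid) or function of time (s).
#' @param duration_s Duration in seconds.
#' @param sampling_rate_hz Sampling rate.
#' @param seed Integer seed.
#' @param channel `"EMG1"` (corrugator) or `"EMG2"` (zygomatic).
#' @return A [sampled_signal()].
#' @export
synthesize_emg <- function(burst_envelope, duration_s, sampling_rate_hz = 256,
                           seed = 1L, channel = "EMG1") {
  n <- ceiling(duration_s * sampling_rate_hz)
  tt <- (seq_len(n) - 1) / sampling_rate_hz
  env <- if (is.function(burst_envelope)) burst_envelope(tt) else
    if (length(burst_envelope) <= 1L) rep(burst_envelope, n) else
    if (length(burst_envelope) == n) burst_envelope else
    stats::approx(seq(0, duration_s, length.out = length(burst_envelope)),
                  burst_envelope, xout = tt, rule = 2)$y
  set.seed(seed)
  x <- env * stats::rnorm(n)
  if (all(x == 0)) x[1:2] <- 0  # keep constructor happy on zero envelope
  sampled_signal(x, sampling_rate_hz, channel, "a.u.")
}

#' Synthesize a skin-conductance signal
#'
#' Tonic baseline plus phasic responses, each an exponential rise toward
#' the event amplitude followed by a slower exponential decay back to
#' baseline — the canonical shape of a skin-conductance response.
#'
#' @param tonic_level Baseline conductance in microsiemens (>= 0).
#' @param phasic_events List of `list(onset_s=, amp_us=)` events.
#' @param duration_s Duration in seconds.
#' @param sampling_rate_hz Sampling rate (32 Hz is sufficient for this
#'   slow signal).
#' @param rise_s,decay_s Rise and decay time constants, seconds.
#' @return A [sampled_signal()] with channel `"SC"`, units `"uS"`.
#' @export
synthesize_sc <- function(tonic_level, phasic_events = list(), duration_s = 60,
                          sampling_rate_hz = 32, rise_s = 0.75, decay_s = 3) {
  if (tonic_level < 0) stop("tonic_level must be >= 0", call. = FALSE)
  n <- ceiling(duration_s * sampling_rate_hz)
  tt <- (seq_len(n) - 1) / sampling_rate_hz
  x <- rep(tonic_level, n)
  for (ev in phasic_events) {
    u <- tt - ev$onset_s
    r <- ifelse(u > 0, (1 - exp(-u / rise_s)) * exp(-u / decay_s), 0)
    x <- x + ev$amp_us * r / max((1 - exp(-tt / rise_s)) * exp(-tt / decay_s),
                                 1e-12)
  }
  sampled_signal(x, sampling_rate_hz, "SC", "uS")
}

#' Specify one group of a synthetic cohort
#'
#' @param group_label `"HighFlex"` or `"LowFlex"`.
#' @param n Number of subjects (>= 2).
#' @param features Named list of `c(mean, sd)` pairs, one per feature.
#' @return A `group_spec` object.
#' @export
group_spec <- function(group_label = c("HighFlex", "LowFlex"), n, features) {
  group_label <- match.arg(group_label)
  stopifnot(n >= 2L, length(features) > 0, !is.null(names(features)))
  for (f in features) {
    stopifnot(length(f) == 2L, f[2L] >= 0)
  }
  structure(list(group_label = group_label, n = as.integer(n),
                 features = features), class = "group_spec")
}

#' Sample a synthetic cohort from group summary statistics
#'
#' Each feature is drawn independently as Normal(mean, sd^2) per group,
#' matching the marginal summaries that published group tables provide;
#' no cross-feature covariance is imposed unless `correlation` is given
#' (one correlation matrix shared by both groups).
#'
#' Group labels come from the generating spec. A `CFI` column is attached
#' (drawn from the spec if a `"CFI"` feature is present, otherwise
#' constructed so the median split reproduces the generating labels),
#' so the median-split stage can be exercised on generated cohorts.
#'
#' @param specs List of [group_spec()] objects with identical feature sets.
#' @param seed Integer seed.
#' @param correlation Optional feature correlation matrix.
#' @return A `data.frame`: `subject_id`, `group`, `CFI`, then one column
#'   per feature.
#' @export
generate_cohort <- function(specs, seed = 1L, correlation = NULL) {
  stopifnot(length(specs) >= 1L)
  fnames <- names(specs[[1L]]$features)
  for (sp in specs) {
    if (!identical(sort(names(sp$features)), sort(fnames))) {
      stop("mismatched feature sets across group specs", call. = FALSE)
    }
  }
  set.seed(seed)
  rows <- list()
  for (sp in specs) {
    p <- length(fnames)
    z <- matrix(stats::rnorm(sp$n * p), sp$n, p)
    if (!is.null(correlation)) {
      z <- z %*% chol(correlation)
    }
    mat <- vapply(seq_along(fnames), function(j) {
      ms <- sp$features[[fnames[j]]]
      ms[1L] + ms[2L] * z[, j]
    }, numeric(sp$n))
    mat <- matrix(mat, nrow = sp$n,
                  dimnames = list(NULL, fnames))
    df <- as.data.frame(mat, check.names = FALSE)
    df$group <- sp$group_label
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("S%02d", seq_len(nrow(out)))
  if (!"CFI" %in% fnames) {
    # synthetic CFI consistent with the generating labels: High above the
    # eventual median, Low below
    base <- ifelse(out$group == "HighFlex", 110, 90)
    out$CFI <- base + stats::runif(nrow(out), -5, 5)
  } else {
    out$CFI <- out[["CFI"]]
  }
  cols <- c("subject_id", "group", "CFI", setdiff(fnames, "CFI"))
  out[, cols, drop = FALSE]
}

#' Write / read a cohort table as TSV
#'
#' Subjects in rows; `subject_id`, `group`, `CFI`, then feature columns.
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @return `path` (write) or the cohort `data.frame` (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
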