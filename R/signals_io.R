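#' Construct a sampled physiological signal
#'
#' The basic container of the package: one channel of uniformly sampled
#' physiology (blood volume pulse, respiration, facial EMG or skin
#' conductance) together with its sampling rate and units.
#'
#' @param samples Numeric vector of samples, in acquisition order.
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param channel Channel label, one of `"BVP"`, `"RSP"`, `"EMG1"`,
#'   `"EMG2"`, `"SC"`.
#' @param units Unit string, e.g. `"a.u."` or `"uS"`.
#' @return An object of class `sampled_signal`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * (0:255) / 256), 256, "RSP")
#' duration(s) # 1 second
sampled_signal <- function(samples, sampling_rate_hz, channel = "BVP",
                           units = "a.u.") {
  channel <- match.arg(channel, signal_channels())
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a sampled_signal needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("samples contain non-finite values; repair or reject before construction",
         call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel = channel, units = units),
    class = "sampled_signal"
  )
}

#' @rdname sampled_signal
#' @export
signal_channels <- function() c("BVP", "RSP", "EMG1", "EMG2", "SC")

#' @rdname sampled_signal
#' @param x A `sampled_signal`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  length(x$samples) / x$sampling_rate_hz
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz (%.2f s), units %s\n",
              x$channel, length(x$samples), x$sampling_rate_hz,
              duration(x), x$units))
  invisible(x)
}

#' Time axis of a signal
#'
#' Sample times in seconds from recording start; the first sample is at 0.
#' @param x A `sampled_signal`.
#' @return Numeric vector of the same length as `x$samples`.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  (seq_along(x$samples) - 1) / x$sampling_rate_hz
}

#' Read a single-channel signal CSV
#'
#' The file dialect is one header block of `key=value` lines (keys
#' `channel`, `sampling_rate_hz`, `units`), then one sample per row.
#' Non-finite samples are rejected by default or repaired by linear
#' interpolation when `repair = TRUE`.
#'
#' @param path Path to the file.
#' @param channel Expected channel label; `NULL` accepts whatever the
#'   header declares.
#' @param repair Repair non-finite samples by linear interpolation
#'   instead of failing.
#' @return A [sampled_signal()].
#' @export
read_signal_csv <- function(path, channel = NULL, repair = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("=", lines, fixed = TRUE)
  n_header <- if (any(!is_header)) which(!is_header)[1L] - 1L else length(lines)
  if (n_header < 1L) {
    stop("format error: no header block (key=value lines) in ", path,
         call. = FALSE)
  }
  kv <- strsplit(lines[seq_len(n_header)], "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  header <- stats::setNames(as.list(vals), keys)
  for (req in c("channel", "sampling_rate_hz")) {
    if (is.null(header[[req]])) {
      stop("format error: header omits `", req, "` in ", path, call. = FALSE)
    }
  }
  fs <- suppressWarnings(as.numeric(header$sampling_rate_hz))
  if (!is.finite(fs) || fs <= 0) {
    stop("format error: invalid sampling_rate_hz `", header$sampling_rate_hz,
         "`", call. = FALSE)
  }
  if (!is.null(channel) && !identical(header$channel, channel)) {
    stop("format error: file declares channel ", header$channel,
         ", expected ", channel, call. = FALSE)
  }
  body <- lines[-seq_len(n_header)]
  body <- body[nzchar(trimws(body))]
  x <- suppressWarnings(as.numeric(body))
  bad_parse <- which(is.na(x) & !toupper(trimws(body)) %in% c("NA", "NAN", "INF", "-INF"))
  if (length(bad_parse)) {
    stop("parse error: non-numeric sample at data row ", bad_parse[1L],
         " (`", body[bad_parse[1L]], "`)", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    if (!repair) {
      stop("signal contains ", sum(!is.finite(x)),
           " non-finite sample(s); use repair = TRUE to interpolate",
           call. = FALSE)
    }
    ok <- which(is.finite(x))
    if (length(ok) < 2L) stop("too few finite samples to repair", call. = FALSE)
    x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  units <- if (is.null(header$units)) "a.u." else header$units
  sampled_signal(x, fs, header$channel, units)
}

#' Write a signal to the package CSV dialect
#'
#' @param x A [sampled_signal()].
#' @param path Output path.
#' @param digits Significant digits written per sample.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "sampled_signal"))
  header <- c(
    paste0("channel=", x$channel),
    paste0("sampling_rate_hz=", format(x$sampling_rate_hz, digits = 15)),
    paste0("units=", x$units)
  )
  writeLines(c(header, formatC(x$samples, digits = digits, format = "g")),
             path)
  invisible(path)
}

#' Write and describe a multi-channel session
#'
#' One file per channel plus a JSON manifest naming the files and the
#' subject they belong to.
#'
#' @param signals Named list of [sampled_signal()] objects; names are
#'   channel labels.
#' @param dir Output directory (created if needed).
#' @param subject_id Subject identifier recorded in the manifest.
#' @return Path of the manifest, invisibly.
#' @export
write_session <- function(signals, dir, subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in signals) {
    f <- file.path(dir, paste0(tolower(s$channel), ".csv"))
    write_signal_csv(s, f)
    files[s$channel] <- basename(f)
  }
  manifest <- file.path(dir, "session.json")
  jsonlite::write_json(list(subject_id = subject_id, files = as.list(files)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a session manifest and its channels
#'
#' @param manifest Path to a `session.json` written by [write_session()].
#' @return List with `subject_id` and `signals` (named list of signals).
#' @export
read_session <- function(manifest) {
  meta <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  sigs <- lapply(names(meta$files), function(ch) {
    read_signal_csv(file.path(dir, meta$files[[ch]]), channel = ch)
  })
  names(sigs) <- names(meta$files)
  list(subject_id = meta$subject_id, signals = sigs)
}

#' Resample a signal to a new rate
#'
#' Rate conversion used to move between the 2048 Hz acquisition rate and
#' the 256 Hz analysis rate (and to 32 Hz for skin conductance). The
#' default polyphase method applies an anti-alias FIR filter when
#' downsampling; the signal is extended by reflection at both ends so the
#' filter transient does not distort the edges. The `"fft"` method
#' truncates or zero-pads the spectrum instead.
#'
#' @param x A [sampled_signal()].
#' @param target_rate_hz New sampling rate in Hz.
#' @param method `"polyphase"` (default) or `"fft"`.
#' @return A [sampled_signal()] at the target rate, same duration within
#'   one target-sample period.
#' @export
resample_signal <- function(x, target_rate_hz, method = c("polyphase", "fft")) {
  stopifnot(inherits(x, "sampled_signal"))
  method <- match.arg(method)
  if (!is.numeric(target_rate_hz) || length(target_rate_hz) != 1L ||
      !is.finite(target_rate_hz) || target_rate_hz <= 0) {
    stop("`target_rate_hz` must be a single positive number", call. = FALSE)
  }
  if (isTRUE(all.equal(target_rate_hz, x$sampling_rate_hz))) return(x)
  n_in <- length(x$samples)
  n_out <- max(2L, round(n_in * target_rate_hz / x$sampling_rate_hz))
  y <- switch(method,
    polyphase = {
      # rational approximation of the rate ratio
      fr <- .rat_approx(target_rate_hz / x$sampling_rate_hz)
      p <- fr[1L]; q <- fr[2L]
      # reflect-pad to absorb the FIR transient
      pad <- min(n_in - 1L, max(32L, ceiling(10 * q)))
      xp <- c(rev(x$samples[2:(pad + 1L)]), x$samples,
              rev(x$samples[(n_in - pad):(n_in - 1L)]))
      yp <- signal::resample(xp, p, q)
      off <- round(pad * p / q)
      yp[(off + 1L):(off + n_out)]
    },
    fft = {
      X <- stats::fft(x$samples)
      Y <- complex(n_out)
      keep <- min(n_in, n_out)
      half <- floor((keep - 1) / 2)
      Y[1L] <- X[1L]
      if (half > 0) {
        Y[2:(half + 1L)] <- X[2:(half + 1L)]
        Y[(n_out - half + 1L):n_out] <- X[(n_in - half + 1L):n_in]
      }
      if (keep %% 2 == 0 && keep > 1) {
        ny <- keep / 2 + 1
        if (n_out > n_in) Y[ny] <- X[ny] / 2 else Y[ny] <- X[ny]
      }
      Re(stats::fft(Y, inverse = TRUE)) / n_in
    })
  sampled_signal(y[seq_len(n_out)], target_rate_hz, x$channel, x$units)
}

# continued-fraction rational approximation p/q of a positive ratio
.rat_approx <- function(r, max_den = 4096L) {
  stopifnot(r > 0)
  a <- floor(r); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1; x <- r - a
  while (x > 1e-12 && q1 < max_den) {
    x <- 1 / x
    a <- floor(x); x <- x - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}
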