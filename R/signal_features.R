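#' Segment a recording into overlapping analysis windows
#'
#' Slides a fixed-length window over the recording with a fixed step. With the
#' defaults (128 ms window, 50 ms step) a real-time loop emits commands at
#' 20 Hz. Window and step durations must convert to whole sample counts at the
#' recording's sampling rate.
#'
#' The number of windows is `floor((N - W) / S) + 1` with N, W, S in samples.
#'
#' @param recording An [emg_recording()] (or a plain numeric matrix, in which
#'   case `fs` must be given).
#' @param window_ms Window length in milliseconds.
#' @param step_ms Step between successive window starts in milliseconds.
#' @param fs Sampling rate, only needed when `recording` is a bare matrix.
#'
#' @return A list of `emg_window` objects, each with elements `samples` (W x 8
#'   matrix) and `start_ms`. A recording shorter than one window yields an
#'   empty list with a warning.
#' @export
segment_windows <- function(recording, window_ms = 128, step_ms = 50,
                            fs = NULL) {
  if (inherits(recording, "emg_recording")) {
    x <- recording$signal
    fs <- recording$fs
  } else {
    x <- as.matrix(recording)
    if (is.null(fs)) stop("fs is required when segmenting a bare matrix")
  }
  if (window_ms <= 0 || step_ms <= 0) {
    stop("window_ms and step_ms must be positive")
  }
  W <- window_ms * fs / 1000
  S <- step_ms * fs / 1000
  if (abs(W - round(W)) > 1e-9 || abs(S - round(S)) > 1e-9) {
    stop(sprintf(
      "window (%g ms) and step (%g ms) must be whole sample counts at fs = %g Hz",
      window_ms, step_ms, fs))
  }
  W <- as.integer(round(W)); S <- as.integer(round(S))
  N <- nrow(x)
  if (N < W) {
    warning(sprintf("recording (%d samples) shorter than one %d-sample window; no windows",
                    N, W))
    return(list())
  }
  starts <- seq.int(0L, N - W, by = S)
  lapply(starts, function(s) {
    structure(
      list(samples = x[(s + 1L):(s + W), , drop = FALSE],
           start_ms = s / fs * 1000),
      class = "emg_window")
  })
}

window_samples <- function(window) {
  if (inherits(window, "emg_window")) window$samples else as.matrix(window)
}

#' Hudgins time-domain features for one window
#'
#' Computes the classic four time-domain features per channel: mean absolute
#' value (MAV), zero-crossing count (ZC), waveform length (WL) and slope-sign
#' change count (SSC). The 8-channel result is flattened to a 32-vector
#' ordered `(MAV, ZC, WL, SSC)` for channel 1, then channel 2, and so on —
#' this ordering is fixed and relied upon by model serialization.
#'
#' Deadbands: a zero crossing between consecutive samples is counted only when
#' they have strictly opposite signs and differ by at least `zc_threshold`; a
#' slope-sign change at sample i is counted when
#' `(x[i]-x[i-1]) * (x[i]-x[i+1]) > 0` and the larger neighbouring difference
#' is at least `ssc_threshold`. Both thresholds default to 0 (the acquisition
#' front end is assumed to pre-condition the signal).
#'
#' @param window An `emg_window` from [segment_windows()] or a samples x
#'   channels matrix with at least 2 samples per channel.
#' @param zc_threshold,ssc_threshold Amplitude deadbands, same units as the
#'   signal.
#'
#' @return Named numeric vector of length `4 * n_channels` with attribute
#'   `normalized = FALSE`.
#' @export
hudgins_features <- function(window, zc_threshold = 0, ssc_threshold = 0) {
  x <- window_samples(window)
  n <- nrow(x)
  if (n < 2L) stop("Hudgins features need at least 2 samples per channel")
  nch <- ncol(x)
  out <- numeric(4L * nch)
  nm <- character(4L * nch)
  for (ch in seq_len(nch)) {
    v <- x[, ch]
    d <- diff(v)
    mav <- mean(abs(v))
    zc <- sum(v[-n] * v[-1L] < 0 & abs(d) >= zc_threshold)
    wl <- sum(abs(d))
    if (n >= 3L) {
      d1 <- v[2:(n - 1)] - v[1:(n - 2)]   # x[i] - x[i-1]
      d2 <- v[2:(n - 1)] - v[3:n]         # x[i] - x[i+1]
      ssc <- sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= ssc_threshold)
    } else {
      ssc <- 0
    }
    k <- (ch - 1L) * 4L
    out[k + 1:4] <- c(mav, zc, wl, ssc)
    nm[k + 1:4] <- paste0(c("mav", "zc", "wl", "ssc"), "_ch", ch)
  }
  names(out) <- nm
  attr(out, "normalized") <- FALSE
  out
}

#' Feature matrix for a list of windows
#'
#' @param windows List of windows from [segment_windows()].
#' @inheritParams hudgins_features
#' @return Numeric matrix, one row per window, 32 columns.
#' @export
feature_matrix <- function(windows, zc_threshold = 0, ssc_threshold = 0) {
  if (length(windows) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = 32))
  }
  t(vapply(windows, hudgins_features, numeric(4L * ncol(window_samples(windows[[1]]))),
           zc_threshold = zc_threshold, ssc_threshold = ssc_threshold))
}

#' Fit / apply a z-score normalizer
#'
#' `fit_normalizer()` learns per-dimension mean and standard deviation from a
#' feature matrix; `apply_normalizer()` z-scores vectors or matrices with the
#' frozen statistics. The standard deviation is the population form (divide by
#' n), so normalizing a two-point set \{0, 2\} yields \{-1, +1\}. Dimensions
#' with (near-)zero spread have their sd floored at `eps` and map to 0, with a
#' warning at fit time. Statistics are frozen at fit time and reused verbatim
#' at inference.
#'
#' @param features Numeric matrix, one feature vector per row; at least 2 rows.
#' @param eps Floor for the per-dimension standard deviation.
#' @return `fit_normalizer()`: an object of class `emg_normalizer` with
#'   elements `mean`, `sd`, `eps`.
#' @export
fit_normalizer <- function(features, eps = 1e-8) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("normalizer must be fitted on at least 2 vectors")
  mu <- colMeans(features)
  sd <- sqrt(colMeans(sweep(features, 2L, mu)^2))
  flat <- sd < eps
  if (any(flat)) {
    warning(sum(flat), " constant feature dimension(s); sd floored at eps")
    sd[flat] <- eps
  }
  structure(list(mean = mu, sd = sd, eps = eps), class = "emg_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer An `emg_normalizer`.
#' @param x Feature vector (length 32) or matrix (rows are vectors).
#' @return `apply_normalizer()`: `x` z-scored, same shape, with attribute
#'   `normalized = TRUE`.
#' @export
apply_normalizer <- function(normalizer, x) {
  stopifnot(inherits(normalizer, "emg_normalizer"))
  if (is.matrix(x)) {
    if (ncol(x) != length(normalizer$mean)) stop("feature dimension mismatch")
    out <- sweep(sweep(x, 2L, normalizer$mean), 2L, normalizer$sd, "/")
  } else {
    if (length(x) != length(normalizer$mean)) stop("feature dimension mismatch")
    out <- (as.numeric(x) - normalizer$mean) / normalizer$sd
    names(out) <- names(x)
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Per-channel root mean square of a window
#'
#' RMS drives the MyoBox avatar directly (one value per electrode) and the
#' spider-plot profile used for coaching.
#'
#' @param window An `emg_window` or samples x channels matrix (nonempty).
#' @return Numeric vector, one nonnegative RMS per channel.
#' @export
channel_rms <- function(window) {
  x <- window_samples(window)
  if (nrow(x) == 0L) stop("cannot compute RMS of an empty window")
  sqrt(colMeans(x^2))
}
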