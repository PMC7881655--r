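# Seedable synthetic surface-EMG generator: movement-specific 8-channel
# activation patterns, trapezoid amplitude modulation, a band-limited Gaussian
# carrier (20-450 Hz, the usual surface-EMG band) and additive baseline
# noise. This is the hardware-free test bed for every other module.

#' Parameters of the synthetic EMG generator
#'
#' Each movement excites the eight channels according to a row of a
#' nonnegative 7 x 8 pattern matrix. The default patterns are orthogonal
#' (movement i excites channel i only); the `overlap` parameter blends every
#' row toward their common mean, so `overlap = 0` keeps the patterns
#' orthogonal and `overlap = 1` makes all movements identical — a dial for
#' class separability. A channel's signal is
#' `pattern_weight * trapezoid(level) * carrier + baseline noise`, with the
#' carrier normalized to unit RMS so a plateau's RMS is approximately
#' `weight * level`.
#'
#' @param fs Sampling rate in Hz.
#' @param patterns Nonnegative 7 x 8 matrix, rows named by [MOVEMENTS];
#'   `NULL` for the orthogonal default.
#' @param carrier_band Band-pass edges in Hz for the Gaussian carrier.
#' @param noise Baseline (rest) noise standard deviation, signal units.
#' @param overlap Pattern overlap in `[0, 1]` (0 orthogonal, 1 identical).
#' @param amplitude_jitter Relative SD of the per-trial amplitude factor,
#'   emulating trial-to-trial contraction variability.
#' @param mvc_amplitude Signal amplitude at full MVC for a unit pattern
#'   weight.
#' @param seed Integer seed; mandatory — every generated recording is a pure
#'   function of the parameters and its seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(fs = 1000, patterns = NULL,
                             carrier_band = c(20, 450), noise = 0.02,
                             overlap = 0, amplitude_jitter = 0.05,
                             mvc_amplitude = 1, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("generator_params requires an explicit integer seed")
  }
  if (is.null(patterns)) {
    patterns <- matrix(0, 7, 8, dimnames = list(MOVEMENTS, paste0("ch", 1:8)))
    for (i in 1:7) patterns[i, i] <- 1
  }
  patterns <- as.matrix(patterns)
  if (!all(dim(patterns) == c(7, 8)) || any(patterns < 0)) {
    stop("patterns must be a nonnegative 7 x 8 matrix")
  }
  if (is.null(rownames(patterns))) rownames(patterns) <- MOVEMENTS
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  stopifnot(fs > 0, noise >= 0, amplitude_jitter >= 0, mvc_amplitude > 0,
            length(carrier_band) == 2L, carrier_band[1] > 0,
            carrier_band[2] < fs / 2)
  structure(list(fs = fs, patterns = patterns, carrier_band = carrier_band,
                 noise = noise, overlap = overlap,
                 amplitude_jitter = amplitude_jitter,
                 mvc_amplitude = mvc_amplitude, seed = as.integer(seed)),
            class = "generator_params")
}

# rows blended toward their common mean: overlap 0 -> original, 1 -> identical
effective_patterns <- function(params) {
  P <- params$patterns
  common <- matrix(colMeans(P), nrow(P), ncol(P), byrow = TRUE)
  (1 - params$overlap) * P + params$overlap * common
}

# unit-RMS band-limited Gaussian carrier (one channel)
band_carrier <- function(n, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate one synthetic EMG recording
#'
#' Builds an 8-channel recording for one trial: the movement's channel
#' pattern, amplitude-modulated by the trapezoid reference at the requested
#' level, carried by band-limited Gaussian noise, plus baseline noise on every
#' channel. A short rest pad surrounds the trapezoid. `"rest"` yields
#' baseline noise only; `mvc = TRUE` produces the movement's MVC baseline
#' (level 1, labelled `"mvc"`).
#'
#' @param movement One of [MOVEMENTS] or `"rest"`.
#' @param level Target fraction of MVC.
#' @param params A [generator_params()].
#' @param posture Posture label stored in the recording.
#' @param seed Seed for this recording; defaults to `params$seed`.
#' @param plateau_s,ramp_s,pad_s Trapezoid plateau, ramp and surrounding rest
#'   durations in seconds.
#' @param mvc Generate the MVC baseline for `movement`.
#' @return An [emg_recording()] with the aligned reference trace.
#' @export
generate_recording <- function(movement, level, params, posture = "armrest",
                               seed = params$seed, plateau_s = 5, ramp_s = 1,
                               pad_s = 0.5, mvc = FALSE) {
  stopifnot(inherits(params, "generator_params"))
  if (!movement %in% c(MOVEMENTS, "rest")) stop("unknown movement '", movement, "'")
  if (mvc) level <- 1
  fs <- params$fs
  pad <- numeric(as.integer(round(pad_s * fs)))
  ref <- if (movement == "rest") numeric(as.integer(round((2 * pad_s + 2 * ramp_s + plateau_s) * fs)))
         else c(pad, trapezoid(level, fs, plateau_s, ramp_s), pad)
  n <- length(ref)
  weights <- if (movement == "rest") numeric(8)
             else effective_patterns(params)[movement, ] * params$mvc_amplitude
  with_local_seed(seed, {
    amp <- max(0, 1 + stats::rnorm(1) * params$amplitude_jitter)
    signal <- vapply(1:8, function(ch) {
      active <- if (weights[ch] > 0) {
        weights[ch] * amp * ref * band_carrier(n, fs, params$carrier_band)
      } else 0
      active + params$noise * stats::rnorm(n)
    }, numeric(n))
    emg_recording(signal, fs,
                  movement = if (mvc) "mvc" else movement,
                  level = if (movement == "rest") 0 else level,
                  posture = posture, reference = ref,
                  mvc_for = if (mvc) movement else NA_character_)
  })
}

#' Generate a session of EMG recording procedures
#'
#' Mirrors the recording protocol: each procedure holds one rest trial, and
#' per movement an MVC baseline followed by one graded trial at each of the
#' three levels (30/60/90% MVC). Postures cycle hanging, armrest, reaching
#' over successive procedures. Per-recording seeds are derived
#' deterministically from `params$seed` and the procedure index.
#'
#' @param params A [generator_params()].
#' @param movements Movements included in the session.
#' @param n_procedures Number of recording procedures.
#' @param levels Graded levels; defaults to [MVC_LEVELS].
#' @param ... Passed to [generate_recording()] (durations).
#' @return List of procedures, each a list
#'   `(index, posture, recordings)`.
#' @export
generate_session <- function(params, movements, n_procedures = 5L,
                             levels = MVC_LEVELS, ...) {
  stopifnot(inherits(params, "generator_params"),
            all(movements %in% MOVEMENTS))
  lapply(seq_len(n_procedures), function(p) {
    posture <- POSTURES[(p - 1L) %% 3L + 1L]
    counter <- 0L
    next_seed <- function() {
      counter <<- counter + 1L
      (params$seed + p * 10000L + counter * 37L) %% 2147483647L
    }
    recs <- list(generate_recording("rest", 0, params, posture,
                                    seed = next_seed(), ...))
    for (mv in movements) {
      recs[[length(recs) + 1L]] <-
        generate_recording(mv, 1, params, posture, seed = next_seed(),
                           mvc = TRUE, ...)
      for (lv in levels) {
        recs[[length(recs) + 1L]] <-
          generate_recording(mv, lv, params, posture, seed = next_seed(), ...)
      }
    }
    list(index = p, posture = posture, recordings = recs)
  })
}

#' Synthetic EMG source for the Motion Test
#'
#' Wraps the generator as the `(movement, level)` stream source the Motion
#' Test expects: each call yields a fresh recording whose plateau covers the
#' trial window. Seeds advance deterministically from `seed` call by call.
#'
#' @param params A [generator_params()].
#' @param seed Base seed for the source's recordings.
#' @param plateau_s Plateau length; at least the trial window (6 s) plus the
#'   hold makes in-band success possible throughout.
#' @param ramp_s,pad_s Trapezoid shape.
#' @return A function `(movement, level) -> emg_recording`.
#' @export
motion_test_source <- function(params, seed = params$seed, plateau_s = 7,
                               ramp_s = 0.5, pad_s = 0) {
  calls <- 0L
  function(movement, level) {
    calls <<- calls + 1L
    generate_recording(movement, level, params,
                       seed = (seed + calls * 101L) %% 2147483647L,
                       plateau_s = plateau_s, ramp_s = ramp_s, pad_s = pad_s)
  }
}
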