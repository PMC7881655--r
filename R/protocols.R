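# Recording-procedure protocol pieces: trapezoid reference, force biofeedback
# estimate, last-five training-set selection, and the Motion Test.

#' Trapezoidal reference trace
#'
#' Piecewise-linear ramp-plateau-ramp template used to elicit graded
#' contractions: 0 up to `level` over `ramp_s`, hold for `plateau_s` (5 s in
#' the protocol), back to 0 over `ramp_s`. Sampled at `fs`.
#'
#' @param level Peak value as a fraction of MVC (0.3 / 0.6 / 0.9 in graded
#'   trials, 1 for MVC baselines; 0 gives an all-zero trace).
#' @param fs Sampling rate in Hz.
#' @param plateau_s Plateau duration in seconds.
#' @param ramp_s Ramp duration in seconds (each side); must be positive.
#' @return Numeric vector of length `(2 * ramp_s + plateau_s) * fs`.
#' @export
trapezoid <- function(level, fs = 1000, plateau_s = 5, ramp_s = 1) {
  if (level < 0 || level > 1) stop("level must lie in [0, 1]")
  if (ramp_s <= 0) stop("ramp duration must be positive")
  nr <- as.integer(round(ramp_s * fs))
  np <- as.integer(round(plateau_s * fs))
  c(level * seq_len(nr) / nr,       # ramp up, ends exactly at level
    rep(level, np),
    level * rev(seq_len(nr) - 1L) / nr)
}

#' Contraction-force estimate for biofeedback
#'
#' Estimates the instantaneous contraction force of a window as the mean over
#' channels of the window MAV divided by the same channel's MAV at maximum
#' voluntary contraction, clipped to `[0, 1.2]`. Monotone in global signal
#' amplitude; this is the trace plotted against the trapezoid reference during
#' recording.
#'
#' @param window An `emg_window` or samples x channels matrix.
#' @param mvc_mav Per-channel MAV at MVC (all entries strictly positive), e.g.
#'   from [mvc_reference()].
#' @return Scalar force estimate in `[0, 1.2]` (fraction of MVC).
#' @export
estimate_force <- function(window, mvc_mav) {
  if (any(mvc_mav <= 0)) stop("MVC reference MAV must be strictly positive on every channel")
  x <- window_samples(window)
  if (ncol(x) != length(mvc_mav)) stop("channel count mismatch with MVC reference")
  mav <- colMeans(abs(x))
  clamp(mean(mav / mvc_mav), 0, 1.2)
}

#' Per-channel MVC reference MAV from an MVC baseline recording
#'
#' Averages the per-channel MAV over the plateau windows of an MVC recording.
#'
#' @param recording An [emg_recording()] with `movement = "mvc"` (or any
#'   recording whose reference has a plateau).
#' @param window_ms,step_ms Windowing parameters.
#' @return Numeric vector of 8 per-channel MAV values.
#' @export
mvc_reference <- function(recording, window_ms = 128, step_ms = 50) {
  w <- plateau_windows(recording, window_ms, step_ms)
  mavs <- vapply(w, function(win) colMeans(abs(win$samples)), numeric(8))
  rowMeans(mavs)
}

#' Select the training set: the most recent five recording procedures
#'
#' The regressor is always retrained on the last five EMG recording
#' procedures (all of them when fewer exist), so the training data track the
#' user's evolving EMG patterns. The protocol requires at least one procedure
#' from each of the three arm postures in the selection; a selection violating
#' that coverage is still returned, with a warning.
#'
#' @param history List of recording procedures ordered oldest to newest; each
#'   procedure is a list with at least elements `posture` and `recordings`.
#' @param n Number of most recent procedures to keep.
#' @return The selected tail of `history`.
#' @export
select_training_data <- function(history, n = 5L) {
  if (length(history) == 0L) stop("recording history is empty")
  sel <- history[seq.int(max(1L, length(history) - n + 1L), length(history))]
  postures <- vapply(sel, function(p) as.character(p$posture %||% NA_character_),
                     character(1))
  missing <- setdiff(POSTURES, postures)
  if (length(missing)) {
    warning("selected procedures do not cover posture(s): ",
            paste(missing, collapse = ", "))
  }
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Force-band margin for a Motion Test level
#'
#' The accepted force band is the target level plus/minus a level-specific
#' margin: 15 percentage points at 30% MVC, 20 at 60%, 30 at 90%.
#'
#' @param level One of 0.3, 0.6, 0.9.
#' @return Margin as a fraction of MVC (0.15 / 0.20 / 0.30).
#' @export
motion_test_margin <- function(level) {
  margins <- c("0.3" = 0.15, "0.6" = 0.20, "0.9" = 0.30)
  key <- format(level)
  if (!key %in% names(margins)) {
    stop("no Motion Test margin defined for level ", level,
         " (levels: 0.3, 0.6, 0.9)")
  }
  unname(margins[key])
}

#' Score one Motion Test trial from per-emission decisions
#'
#' A trial succeeds when the time spent in-criterion — the regressor's largest
#' output is the prompted movement AND its force is within the level's margin
#' — reaches `hold_s` (2 s) before the `window_s` (6 s) trial window elapses.
#' By default the in-criterion time accumulates (interruptions don't reset
#' it); `mode = "consecutive"` requires an unbroken dwell instead.
#'
#' @param predicted Character vector, the argmax movement at each emission.
#' @param force Numeric vector, the estimated force (fraction of MVC) at each
#'   emission.
#' @param dt Emission period in seconds (0.05 at the 50 ms step).
#' @param prompt Prompted movement label.
#' @param level Prompted force level (0.3 / 0.6 / 0.9).
#' @param margin Force-band half-width; defaults to [motion_test_margin()].
#' @param hold_s Required in-criterion time (s).
#' @param window_s Trial window (s).
#' @param mode `"cumulative"` (default) or `"consecutive"`.
#' @return List `(success, time_s)`; failed trials report `time_s = window_s`.
#' @export
motion_test_trial <- function(predicted, force, dt, prompt, level,
                              margin = motion_test_margin(level),
                              hold_s = 2, window_s = 6,
                              mode = c("cumulative", "consecutive")) {
  mode <- match.arg(mode)
  n_steps <- min(length(predicted), length(force), ceiling(window_s / dt))
  acc <- 0
  for (i in seq_len(n_steps)) {
    ok <- predicted[i] == prompt && abs(force[i] - level) <= margin
    acc <- if (ok) acc + dt else if (mode == "consecutive") 0 else acc
    if (acc >= hold_s - 1e-9) {
      return(list(success = TRUE, time_s = i * dt))
    }
  }
  list(success = FALSE, time_s = window_s)
}

#' Run a full Motion Test
#'
#' Prompts each trained movement at each of the three force levels (three
#' trials per movement), streams EMG from `source`, and scores each trial with
#' [motion_test_trial()]. At every emission the regressor output (smoothed
#' with the 4-tap moving average) provides both the decision (argmax movement)
#' and the force (the prompted movement's strength, in MVC fractions — the
#' scale its targets are trained on).
#'
#' @param model A trained `emg_regressor`.
#' @param source Function `(movement, level) -> emg_recording` supplying at
#'   least `window_s` seconds of signal for the prompted contraction.
#' @param movements Movements to test; defaults to the model's.
#' @param levels Force levels; defaults to [MVC_LEVELS].
#' @param window_ms,step_ms Windowing parameters.
#' @param hold_s,window_s,mode Passed to [motion_test_trial()].
#' @param smooth_taps Moving-average length applied to the strength stream.
#' @return Data frame `(movement, level, success, time_s)`, one row per trial.
#' @export
motion_test <- function(model, source, movements = model$movements,
                        levels = MVC_LEVELS, window_ms = 128, step_ms = 50,
                        hold_s = 2, window_s = 6,
                        mode = c("cumulative", "consecutive"),
                        smooth_taps = 4L) {
  mode <- match.arg(mode)
  dt <- step_ms / 1000
  res <- list()
  for (mv in movements) {
    for (lv in levels) {
      rec <- source(mv, lv)
      windows <- segment_windows(rec, window_ms, step_ms)
      S <- predict_strengths(model, feature_matrix(windows))
      if (smooth_taps > 1L && nrow(S) > 0L) {
        S <- apply(S, 2L, function(col) {
          stats::filter(c(rep(0, smooth_taps - 1L), col),
                        rep(1 / smooth_taps, smooth_taps),
                        sides = 1)[smooth_taps:(length(col) + smooth_taps - 1L)]
        })
        S <- matrix(S, ncol = length(model$movements),
                    dimnames = list(NULL, model$movements))
      }
      predicted <- model$movements[max.col(S, ties.method = "first")]
      trial <- motion_test_trial(predicted, S[, mv], dt, mv, lv,
                                 hold_s = hold_s, window_s = window_s,
                                 mode = mode)
      res[[length(res) + 1L]] <- data.frame(
        movement = mv, level = lv, success = trial$success,
        time_s = trial$time_s)
    }
  }
  do.call(rbind, res)
}

#' Write a Motion Test report
#'
#' CSV columns: `movement, level, outcome, time_s`.
#'
#' @param results Data frame from [motion_test()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_motion_test_report <- function(results, path) {
  utils::write.csv(
    data.frame(movement = results$movement, level = results$level,
               outcome = ifelse(results$success, "success", "failure"),
               time_s = results$time_s),
    path, row.names = FALSE)
  invisible(path)
}
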