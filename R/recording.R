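#' Movement, posture and level vocabularies
#'
#' The seven hand/wrist movements driven by the regressor, in the canonical
#' output order used throughout the package; the three recording postures; and
#' the three graded contraction levels (fractions of maximum voluntary
#' contraction, MVC) used by the recording procedure and the Motion Test.
#'
#' @format Character (or numeric) vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
MOVEMENTS <- c(
  "fine_pinch", "lateral_pinch",
  "wrist_rotation_cw", "wrist_rotation_ccw",
  "wrist_flexion", "wrist_extension",
  "hand_open"
)

#' @rdname vocabularies
#' @export
POSTURES <- c("hanging", "armrest", "reaching")

#' @rdname vocabularies
#' @export
MVC_LEVELS <- c(0.3, 0.6, 0.9)

#' Eight-channel surface-EMG recording
#'
#' Container for one trial of multi-channel surface EMG together with the
#' metadata the training protocol needs: the prompted movement, the target
#' contraction level as a fraction of MVC, the arm posture, and the trapezoid
#' reference trace shown to the user (aligned sample-by-sample with the
#' signal).
#'
#' @param signal Numeric matrix, one column per channel (8 columns), one row
#'   per sample. Millivolt-scale arbitrary units.
#' @param fs Sampling rate in Hz. Must be positive.
#' @param movement One of [MOVEMENTS], `"rest"`, or `"mvc"` (an MVC baseline
#'   trial; see `mvc_for`).
#' @param level Target fraction of MVC in `[0, 1]`. Graded protocol trials use
#'   0.3, 0.6 or 0.9; MVC baselines use 1.
#' @param posture One of [POSTURES], or `NA`.
#' @param reference Numeric vector of the same length as the signal giving the
#'   reference force trace (fraction of MVC). Defaults to all zeros.
#' @param mvc_for For `movement = "mvc"`: which movement this baseline belongs
#'   to.
#' @param recorded_at Optional timestamp (any scalar; stored verbatim).
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs, movement, level = NA_real_,
                          posture = NA_character_, reference = NULL,
                          mvc_for = NA_character_, recorded_at = NA) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (ncol(signal) != 8L) {
    stop("an EMG recording must have exactly 8 channels, got ", ncol(signal))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive sampling rate in Hz")
  }
  allowed <- c(MOVEMENTS, "rest", "mvc")
  if (!movement %in% allowed) {
    stop("unknown movement label '", movement, "'")
  }
  if (movement == "mvc" && !mvc_for %in% MOVEMENTS) {
    stop("an 'mvc' recording must name its movement via mvc_for")
  }
  if (!is.na(posture) && !posture %in% POSTURES) {
    stop("posture must be one of: ", paste(POSTURES, collapse = ", "))
  }
  if (is.null(reference)) reference <- numeric(nrow(signal))
  if (length(reference) != nrow(signal)) {
    stop("reference trace must be aligned with the signal (",
         nrow(signal), " samples, got ", length(reference), ")")
  }
  structure(
    list(signal = signal, fs = fs, movement = movement, level = level,
         posture = posture, reference = as.numeric(reference),
         mvc_for = mvc_for, recorded_at = recorded_at),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %s | %.1f s @ %g Hz | level %s | posture %s\n",
    if (x$movement == "mvc") paste0("mvc(", x$mvc_for, ")") else x$movement,
    nrow(x$signal) / x$fs, x$fs,
    ifelse(is.na(x$level), "-", format(x$level)),
    ifelse(is.na(x$posture), "-", x$posture)
  ))
  invisible(x)
}

#' Duration of a recording in milliseconds
#' @param recording An [emg_recording()].
#' @return Duration in ms.
#' @export
recording_duration_ms <- function(recording) {
  stopifnot(inherits(recording, "emg_recording"))
  nrow(recording$signal) / recording$fs * 1000
}
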