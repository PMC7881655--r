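# Strengths -> signed 4-DoF command vector, conflict resolution, 4-tap
# moving-average smoothing, and the offline streaming loop.

DOF_NAMES <- c("pinch", "rotation", "flex_ext", "open")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Combine seven movement strengths into a four-DoF command vector
#'
#' Opposing movements are folded into one signed value per degree of freedom:
#' `pinch = scale * (fine - lateral)` (fine pinch positive, lateral negative),
#' `rotation = scale * (CW - CCW)`, `flex_ext = scale * (flexion - extension)`,
#' and `open = scale * hand_open` (0..100, no opposing movement). Each element
#' is clamped to `[-100, 100]`, then the grip/open conflict is resolved: the
#' hand cannot close in a pinch and open at once, so when both `pinch` and
#' `open` are nonzero the element with the smaller absolute value is discarded
#' (on an exact tie, `open` is discarded).
#'
#' @param strengths Numeric vector of 7 nonnegative strengths ordered as
#'   [MOVEMENTS]. Models trained on fewer movements can pass a named vector;
#'   missing movements count as 0.
#' @param scale Gain from strength units (fractions of MVC) to command units;
#'   the default 100 maps a full-MVC strength to a full-scale command.
#' @return Named command vector `(pinch, rotation, flex_ext, open)`, class
#'   `command_vector`.
#' @export
combine_dofs <- function(strengths, scale = 100) {
  s <- numeric(7); names(s) <- MOVEMENTS
  if (!is.null(names(strengths))) {
    unknown <- setdiff(names(strengths), MOVEMENTS)
    if (length(unknown)) stop("unknown movement(s): ", paste(unknown, collapse = ", "))
    s[names(strengths)] <- strengths
  } else {
    if (length(strengths) != 7L) {
      stop("unnamed strengths must have length 7 (order: ",
           paste(MOVEMENTS, collapse = ", "), ")")
    }
    s[] <- strengths
  }
  if (any(!is.finite(s))) stop("strengths must be finite (no NA/NaN)")
  cmd <- c(
    pinch = clamp(scale * (s[["fine_pinch"]] - s[["lateral_pinch"]]), -100, 100),
    rotation = clamp(scale * (s[["wrist_rotation_cw"]] - s[["wrist_rotation_ccw"]]), -100, 100),
    flex_ext = clamp(scale * (s[["wrist_flexion"]] - s[["wrist_extension"]]), -100, 100),
    open = clamp(scale * s[["hand_open"]], 0, 100)
  )
  resolve_grip_conflict(cmd)
}

#' Resolve the pinch / hand-open conflict
#'
#' When both the pinch element and the open element are nonzero, the one with
#' the smaller absolute value is zeroed (tie: open is zeroed). Idempotent.
#'
#' @param cmd Named command vector `(pinch, rotation, flex_ext, open)`.
#' @return The command vector with at most one of pinch/open nonzero.
#' @export
resolve_grip_conflict <- function(cmd) {
  if (cmd[["pinch"]] != 0 && cmd[["open"]] != 0) {
    if (abs(cmd[["pinch"]]) >= abs(cmd[["open"]])) cmd[["open"]] <- 0
    else cmd[["pinch"]] <- 0
  }
  structure(cmd, class = "command_vector")
}

#' Streaming state for the moving-average post-filter
#'
#' Ring buffer over the last `taps` raw command vectors, zero-filled at start
#' so the first emissions are attenuated rather than delayed.
#'
#' @param taps Filter length; the control loop averages the last 4 regression
#'   outputs.
#' @param n_dof Command vector length.
#' @return A `stream_state` object.
#' @export
stream_state <- function(taps = 4L, n_dof = 4L) {
  structure(list(buffer = matrix(0, taps, n_dof,
                                 dimnames = list(NULL, DOF_NAMES[seq_len(n_dof)])),
                 count = 0L),
            class = "stream_state")
}

#' Apply the moving-average post-filter to one raw command
#'
#' Pushes `cmd` into the ring buffer and returns the elementwise mean of the
#' buffer. The filter has unit DC gain and never leaves the input range; a
#' 0 to 100 step on one DoF produces 25, 50, 75, 100 on successive emissions.
#'
#' @param state A [stream_state()].
#' @param cmd Raw command vector (length matching the buffer).
#' @return List with the updated `state` and the smoothed `command`.
#' @export
moving_average_filter <- function(state, cmd) {
  stopifnot(inherits(state, "stream_state"))
  k <- nrow(state$buffer)
  state$buffer[state$count %% k + 1L, ] <- as.numeric(cmd)
  state$count <- state$count + 1L
  out <- colMeans(state$buffer)
  list(state = state, command = structure(out, class = "command_vector"))
}

#' Run the real-time control loop offline over a recording
#'
#' Slides the feature window over the signal at the step cadence, predicts
#' movement strengths, combines them into a raw command, and smooths with the
#' 4-tap moving average — one command per step (20 Hz at the defaults). The
#' algorithmic delay, window span plus one step (178 ms at the defaults), is
#' attached as attribute `delay_ms`.
#'
#' @param model A trained `emg_regressor` (with its normalizer).
#' @param recording An [emg_recording()] acting as the sample source.
#' @param window_ms,step_ms Windowing parameters.
#' @param scale Strength-to-command gain, see [combine_dofs()].
#' @param taps Post-filter length.
#' @param zc_threshold,ssc_threshold Feature deadbands.
#' @return Data frame `(t_ms, pinch, rotation, flex_ext, open)`, one row per
#'   emission (timestamped at window end), with attribute `delay_ms`.
#' @export
run_stream <- function(model, recording, window_ms = 128, step_ms = 50,
                       scale = 100, taps = 4L,
                       zc_threshold = 0, ssc_threshold = 0) {
  windows <- segment_windows(recording, window_ms, step_ms)
  st <- stream_state(taps)
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    fv <- hudgins_features(windows[[i]], zc_threshold, ssc_threshold)
    s <- predict_strengths(model, fv)
    raw <- combine_dofs(s, scale)
    sm <- moving_average_filter(st, raw)
    st <- sm$state
    rows[[i]] <- c(t_ms = windows[[i]]$start_ms + window_ms, sm$command)
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (length(rows) == 0L) {
    out <- data.frame(t_ms = numeric(), pinch = numeric(), rotation = numeric(),
                      flex_ext = numeric(), open = numeric())
  }
  attr(out, "delay_ms") <- window_ms + step_ms
  out
}

#' Write / read a command log
#'
#' CSV columns: `timestamp_ms, pinch, rotation, flex_ext, open`.
#'
#' @param commands Data frame from [run_stream()].
#' @param path Output CSV path.
#' @return `write_command_log()`: the path, invisibly. `read_command_log()`:
#'   the data frame.
#' @export
write_command_log <- function(commands, path) {
  df <- commands
  names(df)[names(df) == "t_ms"] <- "timestamp_ms"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_command_log
#' @export
read_command_log <- function(path) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "timestamp_ms"] <- "t_ms"
  df
}
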