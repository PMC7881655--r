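# Headless deterministic engines for the two serious games. Both are pure
# state machines: no RNG, no wall clock — the same state and input sequence
# always produce the same trajectory, so episodes are replayable from logs.

#' RMS-to-direction mapping for the MyoBox avatar
#'
#' Direct linear mapping from the eight per-electrode RMS values to a 2-D
#' avatar direction: the vertical component contrasts electrodes 2-4 against
#' 6-8 and the horizontal component contrasts electrodes 1, 2, 8 against 4-6,
#'
#' \deqn{y = (RMS_2 + RMS_3 + RMS_4)/3 - (RMS_6 + RMS_7 + RMS_8)/3}
#' \deqn{x = (RMS_1 + RMS_2 + RMS_8)/3 - (RMS_4 + RMS_5 + RMS_6)/3}
#'
#' The mapping is linear, so scaling every RMS scales the direction.
#'
#' @param rms Numeric vector of 8 nonnegative per-channel RMS values.
#' @return Named vector `c(x, y)`.
#' @export
avatar_direction <- function(rms) {
  if (length(rms) != 8L) stop("avatar_direction needs exactly 8 RMS values")
  if (any(rms < 0)) stop("RMS values must be nonnegative")
  c(x = (rms[1] + rms[2] + rms[8]) / 3 - (rms[4] + rms[5] + rms[6]) / 3,
    y = (rms[2] + rms[3] + rms[4]) / 3 - (rms[6] + rms[7] + rms[8]) / 3)
}

#' MyoBox engine configuration
#'
#' All geometry and gain constants of the headless MyoBox arena. Units are
#' arbitrary arena units; the platform spans `[-platform_width/2,
#' platform_width/2]` at ground level, boxes hover above it, and the ball is
#' driven by `gain * direction` per second. On each level-up the platform
#' narrows by `platform_decrement` down to `platform_min_width`.
#'
#' @param gain Ball speed per unit direction (units/s).
#' @param platform_width Starting platform width.
#' @param platform_min_width Smallest platform the difficulty progression
#'   reaches.
#' @param platform_decrement Width lost per level-up.
#' @param arena_height Ceiling for the ball's vertical position.
#' @param box_radius Collection radius around each box.
#' @param box_points Score for collecting one box.
#' @param n_boxes Boxes per level.
#' @return A `myobox_config` list.
#' @export
myobox_config <- function(gain = 40, platform_width = 60,
                          platform_min_width = 12, platform_decrement = 8,
                          arena_height = 100, box_radius = 5,
                          box_points = 100, n_boxes = 3L) {
  structure(list(gain = gain, platform_width = platform_width,
                 platform_min_width = platform_min_width,
                 platform_decrement = platform_decrement,
                 arena_height = arena_height, box_radius = box_radius,
                 box_points = box_points, n_boxes = as.integer(n_boxes)),
            class = "myobox_config")
}

# deterministic box layout: evenly spread across the platform at fixed heights
myobox_boxes <- function(width, n, height) {
  data.frame(x = seq(-width / 2 * 0.8, width / 2 * 0.8, length.out = n),
             y = height * (seq_len(n) / (n + 1)),
             collected = FALSE)
}

#' Initial MyoBox state
#'
#' @param config A [myobox_config()].
#' @return A `myobox_state`: ball at the platform centre, full platform width,
#'   level 1 boxes pending, score 0.
#' @export
myobox_state <- function(config = myobox_config()) {
  structure(list(ball = c(x = 0, y = 0),
                 platform_width = config$platform_width,
                 boxes = myobox_boxes(config$platform_width, config$n_boxes,
                                      config$arena_height),
                 score = 0, level = 1L, falls = 0L,
                 config = config, events = character()),
            class = "myobox_state")
}

#' Advance MyoBox by one tick
#'
#' Moves the ball by `gain * direction * dt` (vertical position clamped to the
#' arena), collects any box within the collection radius, and applies the two
#' rules of the game: leaving the platform span at ground level costs a life
#' (ball resets, `"fell"` event, score kept — it is monotone within a life),
#' and collecting every box levels up, narrowing the platform toward its
#' configured minimum and laying out fresh boxes.
#'
#' @param state A `myobox_state`.
#' @param direction Named `c(x, y)` direction from [avatar_direction()].
#' @param dt Tick duration in seconds.
#' @return The next `myobox_state`; `$events` holds this tick's events.
#' @export
myobox_step <- function(state, direction, dt) {
  stopifnot(inherits(state, "myobox_state"))
  cfg <- state$config
  state$events <- character()
  state$ball["x"] <- state$ball["x"] + cfg$gain * direction[["x"]] * dt
  state$ball["y"] <- clamp(state$ball["y"] + cfg$gain * direction[["y"]] * dt,
                           0, cfg$arena_height)

  hit <- !state$boxes$collected &
    sqrt((state$boxes$x - state$ball["x"])^2 +
           (state$boxes$y - state$ball["y"])^2) <= cfg$box_radius
  if (any(hit)) {
    state$boxes$collected[hit] <- TRUE
    state$score <- state$score + cfg$box_points * sum(hit)
    state$events <- c(state$events, rep("box_collected", sum(hit)))
  }

  if (all(state$boxes$collected)) {
    state$level <- state$level + 1L
    state$platform_width <- max(cfg$platform_min_width,
                                state$platform_width - cfg$platform_decrement)
    state$boxes <- myobox_boxes(state$platform_width, cfg$n_boxes,
                                cfg$arena_height)
    state$ball <- c(x = 0, y = 0)
    state$events <- c(state$events, "level_up")
  }

  if (state$ball["y"] <= 0 &&
      abs(state$ball["x"]) > state$platform_width / 2) {
    state$ball <- c(x = 0, y = 0)
    state$falls <- state$falls + 1L
    state$events <- c(state$events, "fell")
  }
  state
}

#' Prosthesis Gripper engine configuration
#'
#' Constants of the headless tracking / grasping game. The screen spans
#' `[-100, 100]`; the light drifts outward at `light_speed`, the avatar is
#' driven by the tracking DoF's command, and points accrue while the avatar is
#' within `beam_distance` of the light (and drain beyond `far_distance`).
#' Grasp-phase constants implement the printed rules: a grip activates at a
#' command of magnitude `activation_threshold` (25) with every other DoF at or
#' below `coactivation_max` (24), within `dispense_timeout_s` (10 s); the
#' gripper opens at most `max_aperture_ratio` (1.7) object widths, shows
#' sparks above `sparks_ratio` (1.5), force-closes at the cap, and a clean
#' release awards `release_points` (1000).
#'
#' @param avatar_gain Avatar speed per command unit (units/s per unit).
#' @param light_speed Light drift speed (units/s).
#' @param beam_distance Avatar-to-light distance at which the beam shows and
#'   points accrue.
#' @param far_distance Distance beyond which points drain.
#' @param track_points_rate,track_loss_rate Points gained / lost per second in
#'   the tracking task.
#' @param dwell_s Time the avatar must sit under the stopped light before the
#'   dispenser appears.
#' @param dispense_timeout_s Grip-activation time limit.
#' @param activation_threshold,coactivation_max Grip-activation rule bounds
#'   (command units).
#' @param aperture_rate Aperture change per second at a full-scale command, in
#'   width units.
#' @param max_aperture_ratio,sparks_ratio Aperture caps in object widths.
#' @param fragile_close_rate Closing speed (width units/s) above which a
#'   fragile object breaks at contact.
#' @param release_threshold Open command required to release a grasped object.
#' @param release_points Score awarded for a successful release.
#' @param tracking_dof Which command element drives the tracking avatar
#'   (`"rotation"` early in training, `"flex_ext"` later).
#' @return A `gripper_config` list.
#' @export
gripper_config <- function(avatar_gain = 0.6, light_speed = 25,
                           beam_distance = 10, far_distance = 40,
                           track_points_rate = 10, track_loss_rate = 5,
                           dwell_s = 1, dispense_timeout_s = 10,
                           activation_threshold = 25, coactivation_max = 24,
                           aperture_rate = 150,
                           max_aperture_ratio = 1.7, sparks_ratio = 1.5,
                           fragile_close_rate = 100,
                           release_threshold = 25, release_points = 1000,
                           tracking_dof = c("rotation", "flex_ext")) {
  structure(list(avatar_gain = avatar_gain, light_speed = light_speed,
                 beam_distance = beam_distance, far_distance = far_distance,
                 track_points_rate = track_points_rate,
                 track_loss_rate = track_loss_rate, dwell_s = dwell_s,
                 dispense_timeout_s = dispense_timeout_s,
                 activation_threshold = activation_threshold,
                 coactivation_max = coactivation_max,
                 aperture_rate = aperture_rate,
                 max_aperture_ratio = max_aperture_ratio,
                 sparks_ratio = sparks_ratio,
                 fragile_close_rate = fragile_close_rate,
                 release_threshold = release_threshold,
                 release_points = release_points,
                 tracking_dof = match.arg(tracking_dof)),
            class = "gripper_config")
}

#' Grip-activation rule
#'
#' A grip is activated when the pinch command for the grip matching the
#' dispenser colour reaches magnitude `threshold` (25) with the correct sign —
#' blue objects take a fine pinch (positive pinch), red a lateral pinch
#' (negative) — while every other DoF stays within `coactivation_max` (24) of
#' zero.
#'
#' @param cmd Named command vector `(pinch, rotation, flex_ext, open)`.
#' @param colour Dispenser/object colour, `"blue"` or `"red"`.
#' @param threshold Minimum pinch magnitude.
#' @param coactivation_max Maximum magnitude allowed on the other DoFs.
#' @return `TRUE` when the matching grip activates.
#' @export
grip_activated <- function(cmd, colour, threshold = 25, coactivation_max = 24) {
  colour <- match.arg(colour, c("blue", "red"))
  p <- cmd[["pinch"]]
  others <- c(cmd[["rotation"]], cmd[["flex_ext"]], cmd[["open"]])
  sign_ok <- if (colour == "blue") p > 0 else p < 0
  sign_ok && abs(p) >= threshold && all(abs(others) <= coactivation_max)
}

# deterministic object queue: colours alternate, widths cycle, every 3rd fragile
gripper_object <- function(index) {
  widths <- c(60, 100, 140)
  list(width = widths[(index - 1L) %% 3L + 1L],
       colour = if (index %% 2L == 1L) "blue" else "red",
       fragile = index %% 3L == 0L)
}

#' Initial Prosthesis Gripper state
#'
#' @param config A [gripper_config()].
#' @param phase Starting phase (normally `"tracking"`; tests and sweeps may
#'   start in `"dispense"` or `"grasp"` directly).
#' @param object Object in play, a list `(width, colour, fragile)`; defaults
#'   to the first object of the deterministic queue when starting past
#'   tracking.
#' @param aperture Initial aperture in width units (grasp-phase starts).
#' @return A `gripper_state`.
#' @export
gripper_state <- function(config = gripper_config(),
                          phase = c("tracking", "dispense", "grasp", "release"),
                          object = NULL, aperture = 0) {
  phase <- match.arg(phase)
  if (is.null(object) && phase != "tracking") object <- gripper_object(1L)
  structure(list(phase = phase, avatar = 0, light = 0, light_dir = 1,
                 dwell = 0, phase_timer = 0, score = 0,
                 aperture = aperture,
                 admitted = !is.null(object) && aperture > object$width,
                 active_grip = "none", sparks = FALSE, forced_close = FALSE,
                 object = object, object_index = 1L,
                 config = config, events = character()),
            class = "gripper_state")
}

#' Advance the Prosthesis Gripper by one tick
#'
#' Runs the four-phase state machine on one command vector:
#' \describe{
#'   \item{tracking}{The avatar chases the drifting light under the tracking
#'     DoF; points accrue in the beam and drain when too far. Once the light
#'     reaches the screen edge and the avatar dwells under it for 1 s, the
#'     dispenser appears.}
#'   \item{dispense}{The player must activate the grip matching the dispenser
#'     colour ([grip_activated()]) within 10 s, else back to tracking.}
#'   \item{grasp}{The aperture follows open (opens) and matching pinch
#'     (closes) commands. Hard cap at 1.7 object widths; sparks show above
#'     1.5 widths; reaching the cap force-closes the gripper. The object must
#'     first be admitted (aperture beyond its width) and is grasped when the
#'     aperture closes back onto it with the matching grip; fragile objects
#'     break when the closing speed at contact exceeds the fragile limit.}
#'   \item{release}{Opening again releases the object, awards 1000 points and
#'     returns to tracking with the next object queued.}
#' }
#'
#' @param state A `gripper_state`.
#' @param cmd Named command vector `(pinch, rotation, flex_ext, open)`.
#' @param dt Tick duration in seconds (`dt = 0` re-evaluates derived state
#'   such as the sparks flag without advancing time).
#' @return The next `gripper_state`; `$events` holds this tick's events.
#' @export
gripper_step <- function(state, cmd, dt) {
  stopifnot(inherits(state, "gripper_state"))
  cfg <- state$config
  state$events <- character()

  if (state$phase == "tracking") {
    state$light <- clamp(state$light + cfg$light_speed * state$light_dir * dt,
                         -100, 100)
    state$avatar <- clamp(state$avatar +
                            cfg$avatar_gain * cmd[[cfg$tracking_dof]] * dt,
                          -100, 100)
    d <- abs(state$avatar - state$light)
    if (d <= cfg$beam_distance) {
      state$score <- state$score + cfg$track_points_rate * dt
    } else if (d > cfg$far_distance) {
      state$score <- state$score - cfg$track_loss_rate * dt
    }
    if (abs(state$light) >= 100) {
      state$dwell <- if (d <= cfg$beam_distance) state$dwell + dt else 0
      if (state$dwell >= cfg$dwell_s) {
        state$phase <- "dispense"
        state$object <- gripper_object(state$object_index)
        state$phase_timer <- 0
        state$dwell <- 0
        state$events <- c(state$events, "dispenser_shown")
      }
    }
  } else if (state$phase == "dispense") {
    state$phase_timer <- state$phase_timer + dt
    if (grip_activated(cmd, state$object$colour,
                       cfg$activation_threshold, cfg$coactivation_max)) {
      state$phase <- "grasp"
      state$active_grip <- if (state$object$colour == "blue") "fine" else "lateral"
      state$aperture <- 0
      state$admitted <- FALSE
      state$forced_close <- FALSE
      state$phase_timer <- 0
      state$events <- c(state$events, "grip_activated", "object_dropped")
    } else if (state$phase_timer >= cfg$dispense_timeout_s) {
      state$phase <- "tracking"
      state$light <- 0
      state$light_dir <- -state$light_dir
      state$events <- c(state$events, "dispense_timeout")
    }
  } else if (state$phase == "grasp") {
    w <- state$object$width
    cap <- cfg$max_aperture_ratio * w
    if (state$forced_close) {
      # forced close drives the gripper shut regardless of command
      state$aperture <- 0
      state$admitted <- FALSE
      state$forced_close <- FALSE
    } else {
      grip_sign <- if (state$active_grip == "fine") 1 else -1
      close_cmd <- max(0, grip_sign * cmd[["pinch"]])
      open_cmd <- max(0, cmd[["open"]])
      close_speed <- cfg$aperture_rate * close_cmd / 100
      prev <- state$aperture
      state$aperture <- state$aperture +
        cfg$aperture_rate * open_cmd / 100 * dt - close_speed * dt
      state$aperture <- max(0, state$aperture)
      if (state$aperture > w) state$admitted <- TRUE
      if (state$aperture >= cap) {
        state$aperture <- cap
        state$forced_close <- TRUE
        state$events <- c(state$events, "forced_close")
      } else if (state$admitted && prev > w && state$aperture <= w &&
                 close_cmd > 0) {
        if (isTRUE(state$object$fragile) &&
            close_speed > cfg$fragile_close_rate) {
          state$events <- c(state$events, "object_broken")
          state$phase <- "tracking"
          state$light <- 0
          state$light_dir <- -state$light_dir
          state$aperture <- 0
          state$active_grip <- "none"
          state$object_index <- state$object_index + 1L
        } else {
          state$phase <- "release"
          state$aperture <- w
          state$events <- c(state$events, "object_grasped")
        }
      }
    }
    state$sparks <- state$phase == "grasp" && state$aperture > cfg$sparks_ratio * w
  } else if (state$phase == "release") {
    if (cmd[["open"]] >= cfg$release_threshold) {
      state$score <- state$score + cfg$release_points
      state$phase <- "tracking"
      state$light <- 0
      state$light_dir <- -state$light_dir
      state$aperture <- 0
      state$active_grip <- "none"
      state$sparks <- FALSE
      state$object_index <- state$object_index + 1L
      state$events <- c(state$events, "object_released")
    }
  }
  state
}

#' Run an engine over a sequence of inputs
#'
#' Replays a fixed input sequence through either engine, collecting the score,
#' phase and events of every tick — the headless equivalent of playing an
#' episode, and the basis of the JSON-lines episode log.
#'
#' @param state Initial `myobox_state` or `gripper_state`.
#' @param inputs For MyoBox, a matrix/data frame with columns `x, y` (one
#'   direction per tick); for the gripper, columns
#'   `pinch, rotation, flex_ext, open`.
#' @param dt Tick duration in seconds.
#' @return List `(state, log)` where `log` is a data frame with one row per
#'   tick (`t`, `phase` (gripper), `score`, `events` collapsed with `;`).
#' @export
run_episode <- function(state, inputs, dt) {
  inputs <- as.data.frame(inputs)
  rows <- vector("list", nrow(inputs))
  for (i in seq_len(nrow(inputs))) {
    if (inherits(state, "myobox_state")) {
      state <- myobox_step(state, c(x = inputs$x[i], y = inputs$y[i]), dt)
      rows[[i]] <- data.frame(t = i * dt, phase = NA_character_,
                              score = state$score,
                              events = paste(state$events, collapse = ";"))
    } else {
      cmd <- c(pinch = inputs$pinch[i], rotation = inputs$rotation[i],
               flex_ext = inputs$flex_ext[i], open = inputs$open[i])
      state <- gripper_step(state, cmd, dt)
      rows[[i]] <- data.frame(t = i * dt, phase = state$phase,
                              score = state$score,
                              events = paste(state$events, collapse = ";"))
    }
  }
  list(state = state, log = do.call(rbind, rows))
}

#' Write an episode log as JSON lines
#'
#' One JSON object per tick (`t`, `phase`, `score`, `events`), replayable and
#' diffable.
#'
#' @param log Data frame from [run_episode()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_episode_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
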