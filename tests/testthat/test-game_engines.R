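test_that("avatar direction evaluates the channel-contrast mapping", {
  expect_equal(avatar_direction(rep(1, 8)), c(x = 0, y = 0))
  expect_equal(avatar_direction(c(0, 1, 1, 1, 0, 0, 0, 0)), c(x = 0, y = 1))
  expect_equal(avatar_direction(c(1, 0, 0, 0, 0, 0, 0, 1)),
               c(x = 2 / 3, y = -1 / 3))
  expect_error(avatar_direction(rep(1, 7)), "8")
  expect_error(avatar_direction(c(-1, rep(1, 7))), "nonnegative")

  # linear in the RMS inputs (positive scaling)
  set.seed(61)
  for (i in 1:20) {
    rms <- runif(8)
    c_scale <- runif(1, 0, 5)
    expect_equal(avatar_direction(c_scale * rms),
                 c_scale * avatar_direction(rms), tolerance = 1e-12)
  }
})

test_that("MyoBox moves the ball, penalizes falls and narrows the platform", {
  st <- myobox_state()
  st2 <- myobox_step(st, c(x = 0, y = 0), 0.05)
  expect_equal(st2$ball, st$ball)

  # drive the ball past the platform edge at ground level
  st3 <- st
  for (i in 1:100) {
    st3 <- myobox_step(st3, c(x = 1, y = 0), 0.05)
    if ("fell" %in% st3$events) break
  }
  expect_true("fell" %in% st3$events)
  expect_equal(unname(st3$ball), c(0, 0))
  expect_equal(st3$falls, 1L)

  # collecting all boxes levels up and strictly narrows the platform
  cfg <- myobox_config(platform_width = 20, platform_min_width = 10,
                       platform_decrement = 8, n_boxes = 1, box_radius = 200)
  st <- myobox_state(cfg)
  widths <- st$platform_width
  for (lvl in 1:4) {
    st <- myobox_step(st, c(x = 0, y = 0.1), 0.05)
    expect_true("level_up" %in% st$events)
    widths <- c(widths, st$platform_width)
  }
  expect_equal(widths, c(20, 12, 10, 10, 10))  # clamped at the minimum
  expect_true(all(diff(widths) <= 0))
  expect_equal(st$score, 4 * cfg$box_points)   # score monotone within a life
})

test_that("grip activation implements the +/-25 with others <= +/-24 rule", {
  expect_true(grip_activated(named_cmd(pinch = 25), "blue"))
  expect_false(grip_activated(named_cmd(pinch = 24), "blue"))
  expect_false(grip_activated(named_cmd(pinch = -25), "blue"))  # wrong sign
  expect_true(grip_activated(named_cmd(pinch = -25), "red"))
  expect_false(grip_activated(named_cmd(pinch = 25, rotation = 25), "blue"))
  expect_true(grip_activated(named_cmd(pinch = 25, rotation = -24), "blue"))
  expect_false(grip_activated(named_cmd(pinch = 25, open = 30), "blue"))
})

test_that("the gripper grasp phase caps, sparks and force-closes the aperture", {
  st <- gripper_state(phase = "grasp",
                      object = list(width = 100, colour = "blue", fragile = FALSE))
  st$active_grip <- "fine"
  apertures <- numeric(0)
  forced <- FALSE
  for (i in 1:200) {
    st <- gripper_step(st, named_cmd(open = 100), 0.05)
    apertures <- c(apertures, st$aperture)
    if ("forced_close" %in% st$events) forced <- TRUE
  }
  expect_true(forced)
  expect_equal(max(apertures), 170)             # 1.7 x width, never beyond
  expect_true(any(apertures == 0))              # force close actually closes
  # sparks showed only above 1.5 x width
  sparks_at <- apertures[apertures > 150 & apertures < 170]
  expect_gt(length(sparks_at), 0)
})

test_that("sparks track the 1.5-width boundary exactly", {
  mk <- function(aperture) {
    st <- gripper_state(phase = "grasp",
                        object = list(width = 100, colour = "blue",
                                      fragile = FALSE),
                        aperture = aperture)
    st$active_grip <- "fine"
    gripper_step(st, named_cmd(), 0)$sparks
  }
  expect_false(mk(150))
  expect_true(mk(150.001))
  expect_false(mk(149))
  expect_true(mk(169))
})

test_that("aperture never exceeds 1.7 widths under random command streams", {
  set.seed(71)
  for (rep in 1:5) {
    st <- gripper_state(phase = "grasp",
                        object = list(width = 60, colour = "blue",
                                      fragile = FALSE))
    st$active_grip <- "fine"
    for (i in 1:150) {
      cmd <- named_cmd(pinch = runif(1, -100, 100), open = runif(1, 0, 100))
      st <- gripper_step(st, cmd, runif(1, 0.01, 0.2))
      if (st$phase != "grasp") break
      expect_lte(st$aperture, 1.7 * 60 + 1e-9)
    }
  }
})

test_that("a full grasp-release cycle awards the 1000-point release bonus", {
  st <- gripper_state(phase = "dispense")   # blue object, width 60
  st <- gripper_step(st, named_cmd(pinch = 30), 0.05)
  expect_equal(st$phase, "grasp")
  expect_equal(st$active_grip, "fine")
  # open past the object width (but short of the cap), then close
  for (i in 1:12) st <- gripper_step(st, named_cmd(open = 80), 0.05)
  expect_true(st$admitted)
  for (i in 1:40) {
    st <- gripper_step(st, named_cmd(pinch = 40), 0.05)
    if (st$phase == "release") break
  }
  expect_equal(st$phase, "release")
  score_before <- st$score
  st <- gripper_step(st, named_cmd(open = 50), 0.05)
  expect_equal(st$phase, "tracking")
  expect_equal(st$score, score_before + 1000)
  expect_true("object_released" %in% st$events)
})

test_that("the dispense phase times out after ten seconds", {
  st <- gripper_state(phase = "dispense")
  for (i in 1:201) st <- gripper_step(st, named_cmd(), 0.05)
  expect_equal(st$phase, "tracking")
})

test_that("fragile objects break under a too-fast closing contact", {
  frag <- list(width = 60, colour = "blue", fragile = TRUE)
  close_at <- function(pinch) {
    st <- gripper_state(phase = "grasp", object = frag)
    st$active_grip <- "fine"
    for (i in 1:12) st <- gripper_step(st, named_cmd(open = 80), 0.05)
    for (i in 1:60) {
      st <- gripper_step(st, named_cmd(pinch = pinch), 0.05)
      if (st$phase != "grasp") break
    }
    st
  }
  gentle <- close_at(30)   # closing speed 45 width-units/s < 100
  expect_equal(gentle$phase, "release")
  rough <- close_at(100)   # closing speed 150 width-units/s > 100
  expect_equal(rough$phase, "tracking")
})

test_that("both engines are pure state machines (replay-identical)", {
  set.seed(81)
  dirs <- data.frame(x = runif(60, -1, 1), y = runif(60, -1, 1))
  a <- run_episode(myobox_state(), dirs, 0.05)
  b <- run_episode(myobox_state(), dirs, 0.05)
  expect_identical(a, b)

  cmds <- data.frame(pinch = runif(60, -100, 100), rotation = runif(60, -50, 50),
                     flex_ext = 0, open = runif(60, 0, 100))
  g1 <- run_episode(gripper_state(), cmds, 0.05)
  g2 <- run_episode(gripper_state(), cmds, 0.05)
  expect_identical(g1, g2)

  path <- withr::local_tempfile(fileext = ".jsonl")
  write_episode_log(g1$log, path)
  lines <- readLines(path)
  expect_length(lines, nrow(g1$log))
  expect_equal(jsonlite::fromJSON(lines[1])$t, 0.05)
})

test_that("the tracking task awards and drains points by beam distance", {
  st <- gripper_state()
  # stationary avatar at centre, light drifting away: eventually too far
  for (i in 1:200) st <- gripper_step(st, named_cmd(), 0.05)
  expect_lt(st$score, 0)

  # perfect tracking: drive the avatar at exactly the light speed
  st <- gripper_state()
  match_cmd <- st$config$light_speed / st$config$avatar_gain
  for (i in 1:100) st <- gripper_step(st, named_cmd(rotation = match_cmd), 0.05)
  expect_gt(st$score, 0)
})
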