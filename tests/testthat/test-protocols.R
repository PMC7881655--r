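test_that("the trapezoid reference peaks at the level with a 5 s plateau", {
  tz <- trapezoid(0.9, fs = 1000)
  expect_equal(max(tz), 0.9)
  expect_length(tz, 7000)                      # 1 + 5 + 1 s
  expect_equal(sum(abs(tz - 0.9) < 1e-12), 5001)  # plateau + ramp apex
  expect_equal(trapezoid(0, fs = 100), rep(0, 700))
  expect_error(trapezoid(0.5, ramp_s = 0), "positive")
  expect_error(trapezoid(1.2), "\\[0, 1\\]")
})

test_that("force estimation is the MAV ratio to MVC, clipped and monotone", {
  set.seed(41)
  mvc_win <- matrix(rnorm(256 * 8), 256, 8)
  mvc_mav <- colMeans(abs(mvc_win))
  expect_equal(estimate_force(mvc_win, mvc_mav), 1.0)
  expect_equal(estimate_force(mvc_win / 2, mvc_mav), 0.5)
  expect_equal(estimate_force(matrix(0, 128, 8), mvc_mav), 0)
  expect_equal(estimate_force(mvc_win * 5, mvc_mav), 1.2)  # clipped
  expect_error(estimate_force(mvc_win, rep(0, 8)), "positive")

  # monotone in global amplitude
  forces <- vapply(c(0.2, 0.5, 0.8, 1.1),
                   function(a) estimate_force(mvc_win * a, mvc_mav), numeric(1))
  expect_true(all(diff(forces) > 0))
})

test_that("MVC reference MAV tracks the generator's plateau amplitude", {
  p <- fixture_params(noise = 0)
  mvc <- generate_recording("fine_pinch", 1, p, mvc = TRUE, seed = 51)
  ref <- mvc_reference(mvc)
  expect_length(ref, 8)
  expect_gt(ref[1], 0.5)          # excited channel (unit weight at full MVC)
  expect_lt(max(ref[-1]), 1e-9)   # silent channels, noise-free
})

test_that("training-set selection keeps the most recent five procedures", {
  history <- lapply(1:7, function(i)
    list(index = i, posture = POSTURES[(i - 1) %% 3 + 1], recordings = list()))
  sel <- select_training_data(history)
  expect_length(sel, 5)
  expect_equal(vapply(sel, `[[`, 0, "index"), 3:7)
  # idempotent / order-stable
  expect_identical(select_training_data(history), sel)

  expect_length(select_training_data(history[1:3]), 3)

  armrest_only <- lapply(1:5, function(i)
    list(index = i, posture = "armrest", recordings = list()))
  expect_warning(sel <- select_training_data(armrest_only),
                 "hanging.*reaching")
  expect_length(sel, 5)

  expect_error(select_training_data(list()), "empty")
})

test_that("the margin map is exactly 15/20/30 percentage points", {
  expect_equal(motion_test_margin(0.3), 0.15)
  expect_equal(motion_test_margin(0.6), 0.20)
  expect_equal(motion_test_margin(0.9), 0.30)
  expect_error(motion_test_margin(0.5), "0.3, 0.6, 0.9")
})

test_that("a Motion Test trial succeeds on 2 s in-criterion within 6 s", {
  n <- 120; dt <- 0.05
  always <- motion_test_trial(rep("hand_open", n), rep(0.6, n), dt,
                              "hand_open", 0.6)
  expect_true(always$success)
  expect_equal(always$time_s, 2)

  never <- motion_test_trial(rep("fine_pinch", n), rep(0.6, n), dt,
                             "hand_open", 0.6)
  expect_false(never$success)
  expect_equal(never$time_s, 6)

  # out-of-band force fails even with the right argmax
  off <- motion_test_trial(rep("hand_open", n), rep(0.95, n), dt,
                           "hand_open", 0.6)
  expect_false(off$success)

  # cumulative mode tolerates interruptions; consecutive mode does not
  pred <- rep(c(rep("hand_open", 30), "fine_pinch"), 4)
  frc <- rep(0.6, length(pred))
  cum <- motion_test_trial(pred, frc, dt, "hand_open", 0.6)
  expect_true(cum$success)
  consec <- motion_test_trial(pred, frc, dt, "hand_open", 0.6,
                              mode = "consecutive")
  expect_false(consec$success)

  # success times always lie in [2, 6]
  late <- motion_test_trial(c(rep("x", 60), rep("hand_open", 60)),
                            rep(0.6, 120), dt, "hand_open", 0.6)
  expect_true(late$success)
  expect_gte(late$time_s, 2)
  expect_lte(late$time_s, 6)
})

test_that("a full Motion Test runs three trials per movement and reports them", {
  m <- fixture_model()
  res <- motion_test(m, motion_test_source(fixture_params(), seed = 900))
  expect_equal(nrow(res), 3 * length(fixture_movements))
  expect_equal(as.vector(table(res$movement)), rep(3, 2))
  expect_setequal(unique(res$level), MVC_LEVELS)
  expect_true(all(res$time_s >= 2 & res$time_s <= 6))
  expect_true(all(res$time_s[!res$success] == 6))

  path <- withr::local_tempfile(fileext = ".csv")
  write_motion_test_report(res, path)
  report <- read.csv(path)
  expect_named(report, c("movement", "level", "outcome", "time_s"))
  expect_equal(report$outcome == "success", res$success)
})
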