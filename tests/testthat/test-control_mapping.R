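test_that("opposing movements combine into signed DoFs with clamping", {
  # fine pinch 0.3 vs hand open 0.2: the smaller-magnitude open is discarded
  cmd <- combine_dofs(c(0.3, 0, 0, 0, 0, 0, 0.2))
  expect_equal(unname(cmd), c(30, 0, 0, 0))

  # symmetric rotation cancels
  cmd <- combine_dofs(c(0, 0, 0.5, 0.5, 0, 0, 0))
  expect_equal(cmd[["rotation"]], 0)

  # clamp to the printed range
  cmd <- combine_dofs(c(0, 0, 0, 0, 0, 0, 1.5))
  expect_equal(cmd[["open"]], 100)
  cmd <- combine_dofs(c(2, 0, 0, 0, 0, 0, 0))
  expect_equal(cmd[["pinch"]], 100)

  # named partial strengths from a 2-movement model
  cmd <- combine_dofs(c(hand_open = 0.4, fine_pinch = 0.1))
  expect_equal(unname(cmd), c(0, 0, 0, 40))

  expect_error(combine_dofs(c(NaN, 0, 0, 0, 0, 0, 0)), "finite")
})

test_that("the grip/open conflict rule is idempotent and breaks ties on open", {
  once <- resolve_grip_conflict(named_cmd(pinch = -40, open = 30))
  expect_equal(unname(once), c(-40, 0, 0, 0))
  expect_equal(resolve_grip_conflict(once), once)

  tie <- resolve_grip_conflict(named_cmd(pinch = 25, open = 25))
  expect_equal(unname(tie), c(25, 0, 0, 0))

  open_wins <- resolve_grip_conflict(named_cmd(pinch = 10, open = 60))
  expect_equal(unname(open_wins), c(0, 0, 0, 60))

  set.seed(13)
  for (i in 1:50) {
    cmd <- named_cmd(runif(1, -100, 100), runif(1, -100, 100),
                     runif(1, -100, 100), runif(1, 0, 100))
    r <- resolve_grip_conflict(cmd)
    expect_identical(resolve_grip_conflict(r), r)
    expect_true(r[["pinch"]] == 0 || r[["open"]] == 0 ||
                  (cmd[["pinch"]] == 0 && cmd[["open"]] == 0))
  }
})

test_that("the 4-tap moving average has unit DC gain and the printed step response", {
  st <- stream_state()
  out <- numeric(6)
  for (i in 1:6) {
    r <- moving_average_filter(st, named_cmd(open = 100))
    st <- r$state
    out[i] <- r$command[["open"]]
  }
  expect_equal(out, c(25, 50, 75, 100, 100, 100))

  # constant stream passes through unchanged once the buffer is full
  st <- stream_state()
  for (i in 1:8) {
    r <- moving_average_filter(st, named_cmd(rotation = -42))
    st <- r$state
  }
  expect_equal(r$command[["rotation"]], -42)

  # alternating +/-100 stays bounded with magnitude <= 50 at steady state
  st <- stream_state()
  vals <- numeric(20)
  for (i in 1:20) {
    r <- moving_average_filter(st, named_cmd(pinch = 100 * (-1)^i))
    st <- r$state
    vals[i] <- r$command[["pinch"]]
  }
  expect_true(all(abs(vals) <= 100))
  expect_true(all(abs(vals[5:20]) <= 50))
})

test_that("the filter is linear and never leaves the input range (fuzz)", {
  set.seed(29)
  st1 <- stream_state(); st2 <- stream_state(); st3 <- stream_state()
  for (i in 1:200) {
    a <- named_cmd(runif(1, -100, 100), runif(1, -100, 100),
                   runif(1, -100, 100), runif(1, 0, 100))
    b <- named_cmd(runif(1, -100, 100), runif(1, -100, 100),
                   runif(1, -100, 100), runif(1, 0, 100))
    r1 <- moving_average_filter(st1, a); st1 <- r1$state
    r2 <- moving_average_filter(st2, b); st2 <- r2$state
    r3 <- moving_average_filter(st3, a + b); st3 <- r3$state
    expect_equal(unname(r3$command), unname(r1$command + r2$command),
                 tolerance = 1e-12)
    expect_true(all(r1$command >= -100 & r1$command <= 100))
  }
})

test_that("the offline stream emits at the step cadence with the 178 ms delay", {
  m <- fixture_model()
  rec <- generate_recording("rest", 0, fixture_params(), seed = 314)
  cmds <- run_stream(m, rec)
  # 8 s of signal at 50 ms cadence
  expect_equal(nrow(cmds), floor((nrow(rec$signal) - 128) / 50) + 1)
  expect_equal(unique(round(diff(cmds$t_ms), 9)), 50)
  expect_equal(attr(cmds, "delay_ms"), 178)
  # rest input on a trained model stays near zero
  expect_lt(max(abs(as.matrix(cmds[, -1]))), 15)
  expect_true(all(abs(as.matrix(cmds[, -1])) <= 100))
})

test_that("command logs round-trip through CSV", {
  m <- fixture_model()
  rec <- generate_recording("hand_open", 0.6, fixture_params(), seed = 315)
  cmds <- run_stream(m, rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_command_log(cmds, path)
  back <- read_command_log(path)
  expect_equal(back$pinch, cmds$pinch, tolerance = 1e-9)
  expect_equal(back$t_ms, cmds$t_ms)
})
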