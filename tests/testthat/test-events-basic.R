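test_that("a steady trace is one fixation and a tracked agent is FSM", {
  tt <- toy_trajectory(rbind(c(-8, 3), c(2, 0), c(-8, -9)), c(0, 0, 90),
                       n_frames = 170)
  # gaze frozen at (-8, 3): fixation; agent 1 sits there at frame 1
  xy <- cbind(rep(-8, 170), rep(3, 170))
  ev <- segment_basic(toy_gaze(xy), tt)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")
  expect_equal(ev$f_start, 1)
  expect_equal(ev$f_end, 170)
  # gaze locked on agent 2 moving at 14.5 deg/s -> FSM on agent 2
  xy <- cbind(2 + 14.5 * (0:169) / 85, rep(0, 170))
  ev <- segment_basic(toy_gaze(xy), tt)
  expect_equal(ev$kind, "FSM")
  expect_equal(ev$agents, "2")
})

test_that("FSM agent criteria match a brute-force oracle", {
  tt <- toy_trajectory(rbind(c(0, 0), c(0.5, 0), c(0, 3), c(5, 0)),
                       c(0, 0, 90, 0), n_frames = 100)
  xy <- cbind(14.5 * (0:99) / 85, rep(0, 100))
  g <- toy_gaze(xy)
  ok <- fsm_agent_check(g, tt, 1, 100)
  expect_true(1 %in% ok)       # same path
  expect_true(2 %in% ok)       # 0.5 deg offset, same direction
  expect_false(3 %in% ok)      # orthogonal motion fails the 25-degree rule
  expect_false(4 %in% ok)      # 5 deg away in the first 100 ms
  # randomized offsets against a literal evaluation of the three criteria
  withr::local_seed(8)
  for (i in 1:20) {
    off <- runif(2, -2, 2); ang <- runif(1, 0, 40)
    tt2 <- toy_trajectory(rbind(c(off[1], off[2]), c(9, 9)), c(ang, 0),
                          n_frames = 100)
    got <- 1 %in% fsm_agent_check(g, tt2, 1, 100)
    d <- sqrt((tt2$positions[1, , 1] - g$x)^2 + (tt2$positions[1, , 2] - g$y)^2)
    skip2 <- 3:11
    dirdiff <- abs(ang - 0)
    want <- mean(d[skip2]) < 1 && mean(d) < 4 && dirdiff < 25
    expect_equal(got, want)
  }
})

test_that("slow-event focus sets use the 4-degree mean distance rule", {
  tt <- toy_trajectory(rbind(c(0, 2), c(0, 5), c(3.9, 0)), c(0, 0, 0),
                       n_frames = 100)
  xy <- cbind(rep(0, 100), rep(0, 100))
  g <- toy_gaze(xy)
  fs <- focus_set_slow(g, tt, 1, 20)
  expect_true(1 %in% fs)
  expect_false(2 %in% fs)
  # agent 3 moves away from the gaze; its mean distance decides
  md <- mean(sqrt((tt$positions[3, 1:20, 1])^2 + (tt$positions[3, 1:20, 2])^2))
  expect_equal(3 %in% fs, md < 4)
})

test_that("no event is shorter than its minimum duration and saccades carry no agents", {
  obs <- fix_observer()
  ev <- obs$events
  th <- event_thresholds()
  mins <- c(fixation = th$fixation$min_dur_ms, SSM = th$ssm$min_dur_ms,
            FSM = th$fsm$min_dur_ms, saccade = th$saccade$min_dur_ms)
  dur <- (ev$f_end - ev$f_start + 1) * 1000 / 85
  expect_true(all(dur > mins[ev$kind]))
  expect_true(all(ev$agents[ev$kind == "saccade"] == ""))
  # basic events never overlap
  ord <- order(ev$f_start)
  expect_true(all(diff(ev$f_start[ord]) > 0))
  expect_true(all(ev$f_start[ord][-1] > ev$f_end[ord][-nrow(ev)]))
})

test_that("truth FSM intervals are recovered with large overlap at zero noise", {
  obs <- fix_observer()
  te <- obs$gaze$truth_events
  fsm_t <- te[te$kind == "FSM", ]
  fsm_r <- obs$events[obs$events$kind == "FSM", ]
  cover <- vapply(seq_len(nrow(fsm_t)), function(i) {
    lo <- fsm_t$t_start[i]; hi <- fsm_t$t_end[i]
    ov <- pmin(hi, fsm_r$t_end) - pmax(lo, fsm_r$t_start)
    sum(pmax(0, ov)) / (hi - lo)
  }, numeric(1))
  expect_gt(mean(cover), 0.7)
  expect_gt(mean(cover > 0.6), 0.8)
})

test_that("entirely missing gaze yields an empty event list", {
  g <- toy_gaze(cbind(rep(NA_real_, 100), rep(NA_real_, 100)))
  tt <- toy_trajectory(rbind(c(0, 0), c(3, 0)), c(0, 0), n_frames = 100)
  ev <- segment_basic(g, tt)
  expect_equal(nrow(ev), 0)
})
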