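test_that("observer simulation is deterministic under the seed", {
  tr <- fix_trial()
  a <- simulate_observer(tr, observer_params("group"), seed = 7L)
  b <- simulate_observer(tr, observer_params("group"), seed = 7L)
  expect_identical(a$raw, b$raw)
  expect_identical(a$truth_events, b$truth_events)
})

test_that("density saccade targets maximize the smoothed agent density", {
  # all agents at one point -> that point (zero jitter)
  tt <- toy_trajectory(matrix(rep(c(4, -2.5), 5), ncol = 2, byrow = TRUE),
                       rep(0, 5), n_frames = 10)
  tt$params <- stimulus_params()
  p <- with_seed(1, density_saccade_target(tt, 0, jitter_sd = 0))
  expect_lt(sqrt(sum((p - c(4, -2.5))^2)), 0.5)
  # 5-agent cluster beats 2-agent cluster
  tt <- toy_trajectory(rbind(matrix(rep(c(-6, -6), 5), ncol = 2, byrow = TRUE) +
                               matrix(runif(10, -1, 1), ncol = 2),
                             matrix(rep(c(6, 6), 2), ncol = 2, byrow = TRUE)),
                       rep(0, 7), n_frames = 10)
  tt$params <- stimulus_params()
  p <- with_seed(1, density_saccade_target(tt, 0, jitter_sd = 0))
  expect_lt(sqrt(sum((p - c(-6, -6))^2)), 2.5)
  # exhaustive grid oracle
  tr <- fix_trial()
  p <- with_seed(2, density_saccade_target(tr, 3, jitter_sd = 0))
  g <- seq(-13, 13, by = 0.5)
  ap <- tr$positions[, 3 * 85 + 1, ]
  dens <- matrix(0, length(g), length(g))
  for (a in 1:14)
    dens <- dens + outer(exp(-(g - ap[a, 1])^2 / 8), exp(-(g - ap[a, 2])^2 / 8))
  ij <- arrayInd(which.max(dens), dim(dens))
  expect_equal(p, c(g[ij[1]], g[ij[2]]), tolerance = 1e-9)
})

test_that("truth labels satisfy the event taxonomy invariants", {
  obs <- fix_observer()
  te <- obs$gaze$truth_events
  # basic tier non-overlapping, strictly increasing
  expect_true(all(diff(te$t_start) > 0))
  expect_true(all(te$t_start[-1] >= te$t_end[-nrow(te)] - 1e-9))
  tc <- obs$gaze$truth_complex
  fsm <- te[te$kind == "FSM", ]
  for (i in which(tc$kind == "pursuit"))
    expect_true(any(fsm$t_start < tc$t_end[i] & fsm$t_end > tc$t_start[i]))
})

test_that("single-agent tracking at unit gain moves the gaze at stimulus speed", {
  tr <- fix_trial()
  lg <- simulate_observer(tr, observer_params("single_agent",
                                              pursuit_gain = 1.0,
                                              noise_sd = 0, blink_rate = 0),
                          seed = 9L)
  fg <- preprocess_gaze(lg$raw, n_frames = dim(tr$positions)[2])
  te <- lg$truth_events
  v <- c()
  for (r in which(te$kind == "FSM")) {
    f0 <- floor(te$t_start[r] * 85) + 3
    f1 <- floor(te$t_end[r] * 85) - 1
    if (f1 > f0) v <- c(v, fg$velocity[f0:f1])
  }
  expect_lt(abs(median(v, na.rm = TRUE) - 14.5), 1)  # oscillation amplitude 3
})

test_that("blinks appear as simultaneous missing gaps in both eyes", {
  tr <- fix_trial()
  lg <- simulate_observer(tr, observer_params("group", blink_rate = 20),
                          seed = 11L)
  expect_gt(nrow(lg$blinks), 0)
  for (b in seq_len(nrow(lg$blinks))) {
    ii <- which(lg$raw$time_ms / 1000 >= lg$blinks[b, 1] &
                lg$raw$time_ms / 1000 <= lg$blinks[b, 2])
    expect_true(all(is.na(lg$raw$lx[ii])))
    expect_true(all(is.na(lg$raw$rx[ii])))
    expect_gte(length(ii) * 2, 60)       # at least 60 ms
  }
})

test_that("injected disparity windows are rejected during fusion", {
  tr <- fix_trial()
  lg <- simulate_observer(tr, observer_params("group", noise_sd = 0,
                                              blink_rate = 0,
                                              disparity_inject_deg = 6),
                          seed = 12L)
  fg <- preprocess_gaze(lg$raw, n_frames = dim(tr$positions)[2])
  expect_gt(sum(fg$missing), 0)
})
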