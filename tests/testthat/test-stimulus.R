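test_that("turn sampling is uniform on +/-60 degrees and wraps correctly", {
  withr::local_seed(1)
  u <- step_direction(rep(0, 1e5)) # turns applied to direction 0
  u <- ifelse(u > 180, u - 360, u)
  expect_true(all(u >= -60 & u <= 60))
  ks <- suppressWarnings(ks.test(u, "punif", -60, 60))
  expect_gt(ks$p.value, 0.01)
  # wraparound
  withr::local_seed(2)
  d <- step_direction(rep(350, 1000))
  expect_true(all(d >= 0 & d < 360))
})

test_that("chaser heading matches the atan2 oracle", {
  expect_equal(chaser_heading(c(0, 0), c(1, 0)), 0)
  expect_equal(chaser_heading(c(0, 0), c(0, -1)), 270)
  withr::local_seed(3)
  for (i in 1:50) {
    a <- runif(2, -10, 10); b <- runif(2, -10, 10)
    expect_equal(chaser_heading(a, b),
                 (atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi) %% 360)
  }
  expect_error(chaser_heading(c(1, 1), c(1, 1)), "coincide")
})

test_that("wall reflection mirrors the direction and keeps agents inside", {
  # right wall: 30 degrees -> 150
  r <- reflect_off_wall(c(12.95, 0), 30, 26, 14.5 / 85)
  expect_equal(r$dir, 150)
  # bottom wall: 270 -> 90
  r <- reflect_off_wall(c(0, -12.95), 270, 26, 14.5 / 85)
  expect_equal(r$dir, 90)
  # sweep: post-bounce step length unchanged and position inside
  withr::local_seed(4)
  step <- 14.5 / 85
  for (i in 1:1000) {
    side <- sample(4, 1)
    pos <- switch(side,
                  c(13 - runif(1, 0, step / 2), runif(1, -12, 12)),
                  c(-13 + runif(1, 0, step / 2), runif(1, -12, 12)),
                  c(runif(1, -12, 12), 13 - runif(1, 0, step / 2)),
                  c(runif(1, -12, 12), -13 + runif(1, 0, step / 2)))
    dir <- switch(side, runif(1, -60, 60), runif(1, 120, 240),
                  runif(1, 30, 150), runif(1, 210, 330))
    dir <- dir %% 360
    nxt <- pos + step * c(cospi(dir / 180), sinpi(dir / 180))
    if (all(abs(nxt) <= 13)) next
    r <- reflect_off_wall(pos, dir, 26, step)
    nxt2 <- r$pos + step * c(cospi(r$dir / 180), sinpi(r$dir / 180))
    expect_equal(sqrt(sum((nxt2 - r$pos)^2)), step, tolerance = 1e-12)
    expect_true(all(abs(nxt2) <= 13 + 1e-9))
  }
})

test_that("trial generation satisfies the kinematic invariants", {
  tr <- fix_trial()
  pos <- tr$positions
  # constant speed at every frame for every agent
  for (a in 1:14) {
    sp <- sqrt(diff(pos[a, , 1])^2 + diff(pos[a, , 2])^2) * 85
    expect_lt(max(abs(sp - 14.5)), 1e-9)
  }
  # containment
  expect_lte(max(abs(pos)), 13)
  # DC distance constraint
  expect_gte(min(chase_distance(tr)), 3)
  # reproducibility
  tr2 <- generate_trial(seed = 3L)
  expect_identical(tr$positions, tr2$positions)
})

test_that("NC trials are unconstrained and occur at the configured rate", {
  mins <- vapply(1:8, function(i)
    min(chase_distance(generate_trial(condition = "NC", seed = 100 + i))),
    numeric(1))
  expect_true(any(mins < 3))
  trials <- simulate_trials(20, condition = "mixed", seed = 9)
  conds <- vapply(trials, `[[`, character(1), "condition")
  expect_equal(sum(conds == "NC"), 2)  # 4/40 of 20
})

test_that("scheduled direction changes occur at 5.4 per second on average", {
  rates <- vapply(1:10, function(i) {
    tr <- generate_trial(condition = "NC", seed = 200 + i)
    mean(rowMeans(tr$dir_change_log[-tr$chaser_idx, -1])) * 85
  }, numeric(1))
  expect_lt(abs(mean(rates) - 5.4), 0.4)
})

test_that("heat-seeking chaser converges without walls or chasee turns", {
  run <- with_seed(11, chasescan:::.simulate_pass(
    stimulus_params(trial_duration = 5), constrain = FALSE, walls = FALSE,
    chasee_turns = FALSE))
  d <- chase_distance(run$positions, run$chaser, run$chasee)
  close_at <- which(d < 0.3)[1]
  upto <- if (is.na(close_at)) length(d) else close_at
  expect_true(all(diff(d[1:upto]) <= 1e-9))
})

test_that("nearest-neighbor statistics match a direct oracle", {
  tt <- toy_trajectory(rbind(c(0, 0), c(3, 0), c(-4, 0), c(9, 0)),
                       c(0, 0, 0, 0), n_frames = 10)
  s <- nearest_neighbor_stats(tt)
  expect_equal(s$mean_chase_distance, 3)
  # distractors at -4 and 9: nearest neighbors at distances 4 and 6
  expect_equal(s$mean_nn_distractor, 5)
  # design claim: distractor NN distance close to chase distance in DC trials
  trials <- simulate_trials(15, condition = "dc", seed = 41)
  st <- vapply(trials, function(tr) {
    u <- nearest_neighbor_stats(tr)
    c(u$mean_nn_distractor, u$mean_chase_distance)
  }, numeric(2))
  rel <- abs(mean(st[1, ]) - mean(st[2, ])) / mean(st[1, ])
  expect_lt(rel, 0.25)
})

test_that("trajectory files round-trip through the text format", {
  tr <- fix_trial()
  p <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(tr, p)
  tr2 <- read_trajectory(p)
  expect_equal(tr2$positions, tr$positions, tolerance = 1e-8)
  expect_equal(tr2$chaser_idx, tr$chaser_idx)
  expect_equal(tr2$condition, "DC")
})
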