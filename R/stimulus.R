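# Chase-display stimulus simulator: one chaser pursues a chasee in a
# heat-seeking manner among randomly moving distractors, all at constant
# speed inside an invisible square arena.

#' Stimulus parameters for the chase display
#'
#' Returns the parameter set that defines a chase-display trial: 14 rings of
#' 1 degree diameter moving at 14.5 deg/s inside an invisible 26 x 26 degree
#' arena at 85 Hz, each ring changing direction 5.4 times per second on
#' average by a turn drawn uniformly from +/-60 degrees, with the chaser
#' re-aiming at the chasee at each of its direction changes and at wall
#' contact. In distance-constrained (DC) trials the chaser--chasee distance
#' never drops below `min_chase_dist`.
#'
#' @param n_agents Number of rings (agents).
#' @param ring_diameter Ring diameter in degrees (rendering only; motion uses
#'   ring centers).
#' @param speed Constant agent speed in deg/s.
#' @param dir_change_rate Mean number of scheduled direction changes per agent
#'   per second.
#' @param turn_range Half-range of the uniform turn distribution in degrees.
#' @param arena_side Side of the square arena in degrees.
#' @param min_chase_dist Minimum chaser--chasee distance (deg) enforced in DC
#'   trials.
#' @param frame_rate Display frame rate in Hz.
#' @param trial_duration Trial duration in seconds.
#' @param nc_fraction Fraction of trials run without the distance constraint.
#' @return A list of class `stimulus_params`.
#' @export
stimulus_params <- function(n_agents = 14L, ring_diameter = 1.0, speed = 14.5,
                            dir_change_rate = 5.4, turn_range = 60,
                            arena_side = 26.0, min_chase_dist = 3.0,
                            frame_rate = 85, trial_duration = 30,
                            nc_fraction = 4 / 40) {
  p <- list(n_agents = as.integer(n_agents), ring_diameter = ring_diameter,
            speed = speed, dir_change_rate = dir_change_rate,
            turn_range = turn_range, arena_side = arena_side,
            min_chase_dist = min_chase_dist, frame_rate = frame_rate,
            trial_duration = trial_duration, nc_fraction = nc_fraction)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all stimulus parameters must be numeric")
  if (any(unlist(p[names(p) != "nc_fraction"]) <= 0))
    stop("all stimulus parameters must be positive")
  if (p$turn_range > 180) stop("turn_range must be <= 180 degrees")
  if (p$min_chase_dist >= p$arena_side / 2)
    stop("min_chase_dist must be smaller than half the arena side")
  class(p) <- "stimulus_params"
  p
}

# degree trigonometry helpers
.cosd <- function(a) cospi(a / 180)
.sind <- function(a) sinpi(a / 180)
.wrap360 <- function(a) a %% 360

#' Draw a new movement direction
#'
#' Adds a turn drawn uniformly from `[-turn_range, +turn_range]` degrees to
#' the current movement direction, wrapping the result to `[0, 360)`. Uses
#' the current R random stream.
#'
#' @param current_dir Current direction(s) in degrees (counter-clockwise from
#'   the positive x axis).
#' @param turn_range Half-range of the uniform turn in degrees.
#' @return New direction(s) in degrees in `[0, 360)`.
#' @export
step_direction <- function(current_dir, turn_range = 60) {
  u <- stats::runif(length(current_dir), -turn_range, turn_range)
  .wrap360(current_dir + u)
}

#' Heading from the chaser towards the chasee
#'
#' @param chaser_pos,chasee_pos Numeric length-2 positions (deg).
#' @return Angle in degrees in `[0, 360)` of the vector chaser -> chasee.
#' @export
chaser_heading <- function(chaser_pos, chasee_pos) {
  d <- chasee_pos - chaser_pos
  if (all(d == 0)) stop("chaser and chasee positions coincide")
  .wrap360(atan2(d[2], d[1]) * 180 / pi)
}

#' Mirror a movement direction off the arena walls
#'
#' Given a position and direction whose next step would leave the arena,
#' returns the direction mirrored around the normal of the offending wall
#' (both normals at a corner). The position is returned unchanged: the agent
#' turns at the wall and the next step is taken with the mirrored direction,
#' so every step keeps its full length.
#'
#' @param pos Length-2 position (deg, arena-centered).
#' @param dir Direction in degrees.
#' @param arena_side Arena side length (deg).
#' @param step Step length (deg) used to probe the next position.
#' @return List with elements `pos` and `dir`.
#' @export
reflect_off_wall <- function(pos, dir, arena_side, step) {
  half <- arena_side / 2
  nxt <- pos + step * c(.cosd(dir), .sind(dir))
  if (abs(nxt[1]) > half) dir <- .wrap360(180 - dir)
  if (abs(nxt[2]) > half) dir <- .wrap360(-dir)
  list(pos = pos, dir = dir)
}

# One simulation pass over all frames. Returns positions, direction-change
# log and bounce counts. With `constrain = TRUE` the chaser's heading is
# projected, frame by frame, onto the closest feasible heading that keeps the
# next-frame chaser--chasee distance at or above min_chase_dist (feasible at
# equal speeds: stepping directly away from the chasee's next position never
# decreases the distance). Projection events are boundary handling, like wall
# bounces, and are not logged as scheduled direction changes.
# `walls` and `chasee_turns` exist for property checks.
.simulate_pass <- function(params, constrain = FALSE, walls = TRUE,
                           chasee_turns = TRUE, init = NULL) {
  n <- params$n_agents
  nf <- as.integer(round(params$trial_duration * params$frame_rate))
  step <- params$speed / params$frame_rate
  half <- params$arena_side / 2
  p_change <- params$dir_change_rate / params$frame_rate
  chaser <- 1L; chasee <- 2L
  tr <- params$turn_range
  dmin <- params$min_chase_dist
  others <- setdiff(seq_len(n), chaser)

  if (is.null(init)) {
    pos <- cbind(stats::runif(n, -half + 0.5, half - 0.5),
                 stats::runif(n, -half + 0.5, half - 0.5))
    if (constrain) {
      while (sqrt(sum((pos[chaser, ] - pos[chasee, ])^2)) < dmin)
        pos[chasee, ] <- stats::runif(2, -half + 0.5, half - 0.5)
    }
    dir <- stats::runif(n, 0, 360)
    dir[chaser] <- chaser_heading(pos[chaser, ], pos[chasee, ])
  } else {
    pos <- init$pos; dir <- init$dir
  }

  positions <- array(NA_real_, dim = c(n, nf, 2))
  positions[, 1L, ] <- pos
  changes <- matrix(FALSE, n, nf)
  bounces <- integer(n)
  grid <- c(0, as.vector(rbind(seq(5, 180, by = 5), -seq(5, 180, by = 5))))
  last_dir_c <- dir[chaser]

  for (f in 2:nf) {
    ch <- stats::runif(n) < p_change
    ch[chaser] <- FALSE                  # the chaser homes continuously
    if (!chasee_turns) ch[chasee] <- FALSE
    idx <- which(ch[others] * 1L == 1L)
    if (length(idx)) dir[others[idx]] <- step_direction(dir[others[idx]], tr)
    # exact coincidence can occur in NC trials where the chaser tailgates
    # at near-contact range; the heading is then left unchanged
    if (any(pos[chaser, ] != pos[chasee, ]))
      dir[chaser] <- chaser_heading(pos[chaser, ], pos[chasee, ])
    changes[, f] <- ch

    # chasee and distractors: bounce (pre-step mirror), then step
    if (walls) {
      nxt_o <- pos[others, ] + step * cbind(.cosd(dir[others]), .sind(dir[others]))
      out <- abs(nxt_o[, 1]) > half | abs(nxt_o[, 2]) > half
      for (k in which(out)) {
        i <- others[k]
        dir[i] <- reflect_off_wall(pos[i, ], dir[i], params$arena_side, step)$dir
        bounces[i] <- bounces[i] + 1L
      }
    }
    pos[others, ] <- pos[others, ] +
      step * cbind(.cosd(dir[others]), .sind(dir[others]))

    # chaser: wall contact re-aims it at the chasee; then the minimum-distance
    # constraint projects the heading if the step would come too close
    probe <- function(d) pos[chaser, ] + step * c(.cosd(d), .sind(d))
    inside <- function(q) abs(q[1]) <= half && abs(q[2]) <= half
    nxt_c <- probe(dir[chaser])
    if (walls && !inside(nxt_c)) {
      if (any(pos[chaser, ] != positions[chasee, f - 1L, ]))
        dir[chaser] <- chaser_heading(pos[chaser, ], positions[chasee, f - 1L, ])
      nxt_c <- probe(dir[chaser])
      if (!inside(nxt_c)) {
        dir[chaser] <- reflect_off_wall(pos[chaser, ], dir[chaser],
                                        params$arena_side, step)$dir
        nxt_c <- probe(dir[chaser])
        bounces[chaser] <- bounces[chaser] + 1L
      }
    }
    if (constrain) {
      ok <- function(q) sqrt(sum((q - pos[chasee, ])^2)) >= dmin - 1e-12 &&
        (!walls || inside(q))
      if (!ok(nxt_c)) {
        # closest feasible heading to the heat-seeking one, with a mild
        # course-keeping penalty so boundary riding does not flip between
        # the two tangent sides frame by frame
        cand <- .wrap360(dir[chaser] + grid)
        cost <- abs(grid) + 0.05 * .ang_diff(cand, last_dir_c)
        for (ci in order(cost)) {
          q <- probe(cand[ci])
          if (ok(q)) { dir[chaser] <- cand[ci]; nxt_c <- q; break }
        }
        if (!ok(nxt_c) && any(pos[chaser, ] != pos[chasee, ])) {
          # exact retreat: at equal speeds this never decreases the distance
          away <- chaser_heading(pos[chasee, ], pos[chaser, ])
          q <- probe(away)
          if (ok(q)) { dir[chaser] <- away; nxt_c <- q }
        }
        if (!ok(nxt_c)) {
          # cornered: stay inside the arena and maximize the distance; the
          # trial-level rejection handles any residual violation
          best_d <- -Inf
          for (ci in seq_along(cand)) {
            q <- probe(cand[ci])
            if (walls && !inside(q)) next
            dd <- sqrt(sum((q - pos[chasee, ])^2))
            if (dd > best_d) { best_d <- dd; dir[chaser] <- cand[ci]; nxt_c <- q }
          }
        }
      }
    }
    last_dir_c <- dir[chaser]
    pos[chaser, ] <- nxt_c
    positions[, f, ] <- pos
  }

  list(positions = positions, changes = changes, bounces = bounces,
       chaser = chaser, chasee = chasee)
}

#' Generate a chase-display trial
#'
#' Simulates one trial of the chase display. All agents move at constant
#' speed. The chasee and distractors make scheduled direction changes
#' independently per frame with probability `dir_change_rate / frame_rate`
#' (a uniform `+/-turn_range` degree turn) and bounce off the walls by
#' mirror reflection. The chaser homes on the chasee's current position at
#' every frame (heat-seeking). In `"DC"` trials the chaser's heading is
#' additionally projected, frame by frame, onto the closest feasible heading
#' that keeps the next-frame chaser--chasee distance at or above
#' `min_chase_dist` (always feasible at equal speeds), so the chase rides
#' the minimum-distance boundary and the minimum distance is also close to
#' the average distance; a full pass that still dips below the minimum
#' (degenerate wall corners) is discarded and regenerated from a fresh
#' substream. `"NC"` trials are unconstrained and the chaser trails the
#' chasee at near-contact distance.
#'
#' @param params A `stimulus_params` object.
#' @param condition `"DC"` (distance-constrained) or `"NC"`.
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param max_retries Maximum number of regeneration attempts for DC trials.
#' @return A `trial_trajectory`: list with `positions` (array
#'   `n_agents x n_frames x 2`, deg), `chaser_idx`, `chasee_idx`,
#'   `condition`, `frame_rate`, `dir_change_log` (logical
#'   `n_agents x n_frames` matrix of scheduled changes), `n_bounces`
#'   and `params`.
#' @export
generate_trial <- function(params = stimulus_params(), condition = c("DC", "NC"),
                           seed = 1L, max_retries = 10000L) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "stimulus_params"))
  base_seed <- as.integer(seed %% 2147000000)
  for (attempt in seq_len(max_retries)) {
    run <- with_seed(base_seed + (attempt - 1L), {
      .simulate_pass(params, constrain = condition == "DC")
    })
    if (condition == "NC") break
    dmin <- min(chase_distance(run$positions, run$chaser, run$chasee))
    if (dmin >= params$min_chase_dist - 1e-12) break
    if (attempt == max_retries)
      stop(sprintf("DC constraint not met after %d attempts (seed %d)",
                   max_retries, seed))
  }
  structure(list(positions = run$positions, chaser_idx = run$chaser,
                 chasee_idx = run$chasee, condition = condition,
                 frame_rate = params$frame_rate,
                 dir_change_log = run$changes, n_bounces = run$bounces,
                 params = params, seed = seed),
            class = "trial_trajectory")
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf("chase-display trial: %d agents, %d frames at %g Hz, %s\n",
              dim(x$positions)[1], dim(x$positions)[2], x$frame_rate,
              x$condition))
  cat(sprintf("  chaser %d -> chasee %d, min distance %.2f deg\n",
              x$chaser_idx, x$chasee_idx,
              min(chase_distance(x$positions, x$chaser_idx, x$chasee_idx))))
  invisible(x)
}

#' Per-frame chaser--chasee distance
#'
#' @param positions Agent position array `n_agents x n_frames x 2` or a
#'   `trial_trajectory`.
#' @param chaser,chasee Agent indices (taken from the trajectory if omitted).
#' @return Numeric vector of distances (deg), one per frame.
#' @export
chase_distance <- function(positions, chaser = NULL, chasee = NULL) {
  if (inherits(positions, "trial_trajectory")) {
    chaser <- positions$chaser_idx; chasee <- positions$chasee_idx
    positions <- positions$positions
  }
  sqrt((positions[chaser, , 1] - positions[chasee, , 1])^2 +
       (positions[chaser, , 2] - positions[chasee, , 2])^2)
}

#' Nearest-neighbor and chase-distance summary
#'
#' Computes, over all frames, the mean distance from each distractor to its
#' nearest neighboring agent and the mean chaser--chasee distance. The arena
#' size and agent count of the display were chosen so that these two means
#' roughly agree, denying observers a trivial proximity cue.
#'
#' @param traj A `trial_trajectory`.
#' @return List with `mean_nn_distractor` and `mean_chase_distance` (deg).
#' @export
nearest_neighbor_stats <- function(traj) {
  stopifnot(inherits(traj, "trial_trajectory"))
  pos <- traj$positions
  n <- dim(pos)[1]; nf <- dim(pos)[2]
  distractors <- setdiff(seq_len(n), c(traj$chaser_idx, traj$chasee_idx))
  nn_sum <- 0; nn_n <- 0
  for (f in seq_len(nf)) {
    p <- pos[, f, ]
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    nn_sum <- nn_sum + sum(apply(d[distractors, , drop = FALSE], 1, min))
    nn_n <- nn_n + length(distractors)
  }
  list(mean_nn_distractor = nn_sum / nn_n,
       mean_chase_distance = mean(chase_distance(traj)))
}

#' Write / read a trajectory as plain text
#'
#' One `key=value` header block, then one line per frame: the frame index
#' followed by x,y pairs for every agent in fixed order.
#'
#' @param traj A `trial_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trial_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trial_trajectory"))
  n <- dim(traj$positions)[1]; nf <- dim(traj$positions)[2]
  hdr <- c(sprintf("# n_agents=%d", n), sprintf("# n_frames=%d", nf),
           sprintf("# frame_rate=%g", traj$frame_rate),
           sprintf("# chaser_idx=%d", traj$chaser_idx),
           sprintf("# chasee_idx=%d", traj$chasee_idx),
           sprintf("# condition=%s", traj$condition))
  m <- matrix(NA_real_, nf, 1 + 2 * n)
  m[, 1] <- seq_len(nf)
  for (a in seq_len(n)) m[, 2 * a + c(0, 1)] <- traj$positions[a, , ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# *", "", hdr), "="))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  n <- as.integer(vals["n_agents"]); nf <- as.integer(vals["n_frames"])
  m <- utils::read.table(text = lines[!grepl("^#", lines)])
  positions <- array(NA_real_, dim = c(n, nf, 2))
  for (a in seq_len(n)) {
    positions[a, , 1] <- m[[2 * a]]
    positions[a, , 2] <- m[[2 * a + 1]]
  }
  structure(list(positions = positions,
                 chaser_idx = as.integer(vals["chaser_idx"]),
                 chasee_idx = as.integer(vals["chasee_idx"]),
                 condition = unname(vals["condition"]),
                 frame_rate = as.numeric(vals["frame_rate"]),
                 dir_change_log = NULL, n_bounces = NULL,
                 params = NULL, seed = NA_integer_),
            class = "trial_trajectory")
}

#' Simulate a batch of trials
#'
#' @param n_trials Number of trials.
#' @param params A `stimulus_params` object.
#' @param condition `"dc"`, `"nc"` or `"mixed"` (DC/NC in the proportion
#'   `1 - nc_fraction : nc_fraction`, NC trials placed by random draw).
#' @param seed Integer master seed; trial `i` uses substream `seed + i`.
#' @return List of `trial_trajectory` objects.
#' @export
simulate_trials <- function(n_trials, params = stimulus_params(),
                            condition = c("mixed", "dc", "nc"), seed = 1L) {
  condition <- match.arg(condition)
  seed <- as.numeric(seed) %% 2000000   # keep derived seeds inside 32 bits
  conds <- switch(condition,
    dc = rep("DC", n_trials),
    nc = rep("NC", n_trials),
    mixed = {
      n_nc <- round(params$nc_fraction * n_trials)
      x <- rep("DC", n_trials)
      if (n_nc > 0) {
        idx <- with_seed(as.integer(seed %% 2147480000),
                         sample.int(n_trials, n_nc))
        x[idx] <- "NC"
      }
      x
    })
  lapply(seq_len(n_trials), function(i)
    generate_trial(params, conds[i], seed = seed * 1000 + i))
}
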