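# Basic oculomotor events: fixations, saccades, slow smooth movement (SSM)
# and fast smooth movement (FSM), segmented from the fused 85 Hz gaze by
# velocity, acceleration and duration thresholds, with gaze-agent criteria
# for FSM and focused-agent sets for the slow events.

#' Threshold table for basic event identification
#'
#' Velocity bands (deg/s), acceleration bounds (deg/s^2) and minimum
#' durations (ms) per event kind. Thresholds act on event-level statistics:
#' a saccade needs peak velocity above 21 and peak acceleration above 4000;
#' the other kinds are judged on the run's median velocity (with a small
#' fraction of frames allowed outside the band, tolerating the velocity
#' oscillations of smooth eye movement) and its 95th-percentile
#' acceleration. The SSM band contains the FSM band; the FSM band is
#' centered on the 14.5 deg/s agent speed.
#'
#' @return A nested list of class `event_thresholds`.
#' @export
event_thresholds <- function() {
  structure(list(
    fixation = list(v = c(0, 6), acc_max = 800, min_dur_ms = 80),
    ssm = list(v = c(4, 21), acc_max = 800, min_dur_ms = 80),
    fsm = list(v = c(9, 21), acc_max = 800, min_dur_ms = 100),
    saccade = list(v_min = 21, acc_min = 4000, min_dur_ms = 20)
  ), class = "event_thresholds")
}

# event-level statistics of a frame run, excluding transition frames at the
# run edges (derivatives there are contaminated by the adjacent saccade)
.run_stats <- function(vel, acc) {
  n <- length(vel)
  trim <- if (n >= 9) 2L else if (n >= 5) 1L else 0L
  idx <- (1 + trim):(n - trim)
  list(v_med = stats::median(vel[idx]),
       v = vel[idx],
       acc95 = if (all(is.na(acc[idx]))) Inf else
         stats::quantile(acc[idx], 0.95, names = FALSE, na.rm = TRUE),
       n = n)
}

#' Agents qualifying a candidate interval as fast smooth movement
#'
#' An agent qualifies when (1) the mean gaze-agent distance over the first
#' 100 ms is below 1 degree, (2) the mean distance over the whole interval
#' is below 4 degrees, and (3) the median absolute angular difference
#' between the gaze and agent motion directions is below 25 degrees. The
#' interval counts as FSM when at least one agent qualifies.
#'
#' @param gaze A `fused_gaze` data frame.
#' @param traj A `trial_trajectory` on the same frame base.
#' @param f_start,f_end Frame range of the candidate interval.
#' @return Integer vector of qualifying agent indices.
#' @export
fsm_agent_check <- function(gaze, traj, f_start, f_end) {
  frames <- f_start:f_end
  n_agents <- dim(traj$positions)[1]
  gxy <- cbind(gaze$x[frames], gaze$y[frames])
  # the initial 100 ms window skips the first two frames of the run, which
  # carry the tail of the preceding saccade after smoothing
  skip <- if (length(frames) > 11) 2L else 0L
  first <- frames[skip + seq_len(min(length(frames) - skip, 9L))]
  gdx <- c(diff(gaze$x[frames]), NA)
  gdy <- c(diff(gaze$y[frames]), NA)
  g_ang <- .wrap360(atan2(gdy, gdx) * 180 / pi)
  ok <- integer(0)
  for (a in seq_len(n_agents)) {
    pa <- traj$positions[a, frames, ]
    d <- sqrt((pa[, 1] - gxy[, 1])^2 + (pa[, 2] - gxy[, 2])^2)
    d1 <- sqrt((traj$positions[a, first, 1] - gaze$x[first])^2 +
               (traj$positions[a, first, 2] - gaze$y[first])^2)
    if (mean(d1) >= 1 || mean(d) >= 4) next
    adx <- c(diff(pa[, 1]), NA)
    ady <- c(diff(pa[, 2]), NA)
    a_ang <- .wrap360(atan2(ady, adx) * 180 / pi)
    dd <- .ang_diff(g_ang, a_ang)
    if (stats::median(dd, na.rm = TRUE) < 25) ok <- c(ok, a)
  }
  ok
}

#' Focused agents of a fixation or slow-smooth-movement interval
#'
#' All agents whose mean distance to the gaze over the interval is below
#' 4 degrees.
#'
#' @inheritParams fsm_agent_check
#' @return Integer vector of agent indices.
#' @export
focus_set_slow <- function(gaze, traj, f_start, f_end) {
  frames <- f_start:f_end
  md <- vapply(seq_len(dim(traj$positions)[1]), function(a) {
    mean(sqrt((traj$positions[a, frames, 1] - gaze$x[frames])^2 +
              (traj$positions[a, frames, 2] - gaze$y[frames])^2))
  }, numeric(1))
  which(md < 4)
}

#' Segment fused gaze into basic events
#'
#' First, candidate saccades are taken as contiguous runs of frames with
#' velocity above the saccade threshold; a run qualifies when its peak
#' acceleration and duration also pass. The remaining coded stretches
#' between saccade candidates are then tested, as units, in the order
#' FSM, SSM, fixation (FSM first because its velocity band lies inside the
#' SSM band, and SSM is defined as smooth movement that does not qualify as
#' FSM). Runs failing every test are left uncoded. A fraction
#' `band_tol` of frames may fall outside the velocity band, tolerating
#' smooth-movement velocity oscillations. Missing frames break runs.
#'
#' @param gaze A `fused_gaze` data frame.
#' @param traj A `trial_trajectory` on the same frame base (required for
#'   the FSM agent criteria and focus sets).
#' @param thresholds An `event_thresholds` list.
#' @param band_tol Allowed out-of-band frame fraction.
#' @param frame_rate Frame rate in Hz.
#' @return A `basic_events` data frame: `kind`, `f_start`, `f_end`,
#'   `t_start`, `t_end`, `agents` (comma-separated agent indices, empty for
#'   saccades).
#' @export
segment_basic <- function(gaze, traj, thresholds = event_thresholds(),
                          band_tol = 0.1, frame_rate = 85) {
  th <- thresholds
  n <- nrow(gaze)
  coded <- !gaze$missing & !is.na(gaze$velocity)
  if (!any(coded)) {
    return(structure(data.frame(kind = character(0), f_start = integer(0),
                                f_end = integer(0), t_start = numeric(0),
                                t_end = numeric(0), agents = character(0)),
                     class = c("basic_events", "data.frame")))
  }
  vel <- gaze$velocity; acc <- gaze$acceleration
  dur_ms <- function(f0, f1) (f1 - f0 + 1) * 1000 / frame_rate

  # saccade candidates: fast frames; qualified by peak acceleration+duration
  fast <- coded & vel > th$saccade$v_min
  sac_runs <- .runs_true(fast)
  sacc <- list()
  for (i in seq_len(nrow(sac_runs))) {
    f0 <- sac_runs$start[i]; f1 <- sac_runs$end[i]
    if (dur_ms(f0, f1) > th$saccade$min_dur_ms &&
        isTRUE(max(acc[f0:f1], na.rm = TRUE) > th$saccade$acc_min))
      sacc[[length(sacc) + 1L]] <- data.frame(
        kind = "saccade", f_start = f0, f_end = f1,
        t_start = gaze$time[f0], t_end = gaze$time[f1], agents = "")
  }

  # slow runs: coded frames that are not fast (all fast frames break runs,
  # whether or not they qualified as saccades)
  slow_runs <- .runs_true(coded & !fast)
  slow <- list()
  for (i in seq_len(nrow(slow_runs))) {
    f0 <- slow_runs$start[i]; f1 <- slow_runs$end[i]
    if (f1 - f0 + 1 < 3) next
    st <- .run_stats(vel[f0:f1], acc[f0:f1])
    kind <- NULL; agents <- integer(0)
    in_band <- function(b) st$v_med >= b[1] && st$v_med <= b[2] &&
      mean(st$v < b[1] | st$v > b[2]) <= band_tol
    if (dur_ms(f0, f1) > th$fsm$min_dur_ms && in_band(th$fsm$v) &&
        st$acc95 < th$fsm$acc_max) {
      agents <- fsm_agent_check(gaze, traj, f0, f1)
      if (length(agents)) kind <- "FSM"
    }
    if (is.null(kind) && dur_ms(f0, f1) > th$ssm$min_dur_ms &&
        in_band(th$ssm$v) && st$acc95 < th$ssm$acc_max) {
      kind <- "SSM"
      agents <- focus_set_slow(gaze, traj, f0, f1)
    }
    if (is.null(kind) && dur_ms(f0, f1) > th$fixation$min_dur_ms &&
        in_band(th$fixation$v) && st$acc95 < th$fixation$acc_max) {
      kind <- "fixation"
      agents <- focus_set_slow(gaze, traj, f0, f1)
    }
    if (!is.null(kind))
      slow[[length(slow) + 1L]] <- data.frame(
        kind = kind, f_start = f0, f_end = f1,
        t_start = gaze$time[f0], t_end = gaze$time[f1],
        agents = paste(agents, collapse = ","))
  }
  out <- rbind(do.call(rbind, sacc), do.call(rbind, slow))
  if (is.null(out))
    out <- data.frame(kind = character(0), f_start = integer(0),
                      f_end = integer(0), t_start = numeric(0),
                      t_end = numeric(0), agents = character(0))
  out <- out[order(out$f_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("basic_events", "data.frame"))
}

#' Per-frame label vector from an event table
#'
#' @param events A `basic_events` data frame (or any data frame with
#'   `f_start`, `f_end`, `kind`).
#' @param n_frames Length of the output.
#' @return Character vector with `"none"` for uncoded frames.
#' @export
events_to_frames <- function(events, n_frames) {
  lab <- rep("none", n_frames)
  for (i in seq_len(nrow(events)))
    lab[events$f_start[i]:events$f_end[i]] <- events$kind[i]
  lab
}

#' Per-frame labels from truth event times
#'
#' Converts the time-stamped truth labels of a `labeled_gaze` to per-frame
#' labels at the display frame rate; saccade subtypes collapse onto
#' `"saccade"`.
#'
#' @param truth A data frame with `kind`, `t_start`, `t_end`.
#' @param n_frames Number of display frames.
#' @param frame_rate Frame rate (Hz).
#' @param collapse_saccades Map `saccade_ES`/`saccade_CS` to `saccade`?
#' @return Character vector of length `n_frames`.
#' @export
truth_to_frames <- function(truth, n_frames, frame_rate = 85,
                            collapse_saccades = TRUE) {
  lab <- rep("none", n_frames)
  for (i in seq_len(nrow(truth))) {
    f0 <- max(1L, floor(truth$t_start[i] * frame_rate) + 1L)
    f1 <- min(n_frames, floor(truth$t_end[i] * frame_rate) + 1L)
    k <- truth$kind[i]
    if (collapse_saccades && k %in% c("saccade_ES", "saccade_CS"))
      k <- "saccade"
    lab[f0:f1] <- k
  }
  lab
}
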