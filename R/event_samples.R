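# Event-locked sample extraction: spatiotemporal windows around detection
# responses, saccade onsets and smooth-movement episodes, aligned by gaze
# or dominant motion direction.

# gaze motion direction around a frame (mean displacement over +/- span
# frames); NA if the gaze barely moves
.gaze_direction <- function(gaze, frame, span = 3, min_speed = 2) {
  f0 <- max(1L, frame - span); f1 <- min(nrow(gaze), frame + span)
  dx <- gaze$x[f1] - gaze$x[f0]; dy <- gaze$y[f1] - gaze$y[f0]
  if (is.na(dx) || is.na(dy)) return(NA_real_)
  sp <- sqrt(dx^2 + dy^2) / (f1 - f0) * 85
  if (sp < min_speed) return(NA_real_)
  .wrap360(atan2(dy, dx) * 180 / pi)
}

#' Samples locked to exploration or catch-up saccade onsets
#'
#' One sample per labeled saccade: the time lock is the saccade onset, the
#' positional lock the saccade target (gaze position at saccade end), and
#' the sample is rotated to the dominant agent motion direction around the
#' lock. Windows that would leave the trial are dropped.
#'
#' @param traj A `trial_trajectory`.
#' @param gaze The matching `fused_gaze`.
#' @param basics A `basic_events` data frame.
#' @param labels Saccade labels from [label_saccades()].
#' @param class `"ES"` for exploration saccades, or the catch-up order to
#'   select (`"CS1"`, `"CS2"`, ..., or `"CS"` for all catch-up saccades).
#' @param spec A `sample_spec` (the +/-400 ms saccade window by default).
#' @return List of `aligned_sample` objects.
#' @export
saccade_samples <- function(traj, gaze, basics, labels,
                            class = c("ES", "CS1", "CS"),
                            spec = sample_spec("saccade_onset")) {
  class <- if (is.character(class)) class[1] else class
  sel <- if (class == "ES") which(labels$label == "ES")
  else if (class == "CS") which(labels$label == "CS")
  else which(labels$label == "CS" &
             labels$cs_order == as.integer(sub("CS", "", class)))
  out <- list()
  for (k in sel) {
    r <- labels$row[k]
    lock_frame <- basics$f_start[r]
    end_frame <- basics$f_end[r]
    lock_pos <- c(gaze$x[end_frame], gaze$y[end_frame])
    if (anyNA(lock_pos)) next
    s <- tryCatch(extract_sample(traj, lock_frame, lock_pos, spec),
                  error = function(e) NULL)
    if (!is.null(s)) { s$label <- class; out[[length(out) + 1L]] <- s }
  }
  out
}

#' Samples locked to the detection response
#'
#' The time lock sits 200 ms before the button press and the window covers
#' the preceding 800 ms; the positional lock is the gaze position at the
#' lock. Samples are aligned to the gaze direction when the gaze is moving
#' (as during pursuit) and to the dominant agent motion direction
#' otherwise. Samples with missing gaze at the lock are dropped.
#'
#' @param traj A `trial_trajectory`.
#' @param gaze The matching `fused_gaze`.
#' @param press_time Button-press time in seconds.
#' @param spec A `sample_spec`; the default window is `[-0.8, 0)` seconds
#'   around the lock.
#' @param lock_lag Lag between lock and button press (s).
#' @return An `aligned_sample`, or `NULL` if the sample cannot be formed.
#' @export
detection_sample <- function(traj, gaze, press_time,
                             spec = sample_spec("detection", t_lo = -0.8,
                                                t_hi = 0, shape = "ring"),
                             lock_lag = 0.2) {
  lock_frame <- floor((press_time - lock_lag) * traj$frame_rate) + 1L
  if (lock_frame < 1 || lock_frame > nrow(gaze)) return(NULL)
  lock_pos <- c(gaze$x[lock_frame], gaze$y[lock_frame])
  if (anyNA(lock_pos)) return(NULL)
  ang <- .gaze_direction(gaze, lock_frame)
  if (is.na(ang)) ang <- NULL
  tryCatch(extract_sample(traj, lock_frame, lock_pos, spec, angle = ang),
           error = function(e) NULL)
}

#' Variable-length samples of smooth-movement episodes
#'
#' One sample per smooth episode (maximal stretch of consecutive SSM/FSM
#' events within a pursuit), locked at the episode start, midpoint or end,
#' aligned to the gaze direction at the lock, optionally keeping only the
#' pursued agents.
#'
#' @param traj A `trial_trajectory`.
#' @param gaze The matching `fused_gaze`.
#' @param basics A `basic_events` data frame.
#' @param complexes The matching `complex_events`.
#' @param lock `"start"`, `"mid"` or `"end"`.
#' @param spec A `sample_spec`; `agent_filter = "pursued_only"` restricts
#'   each sample to the episode's focused agents.
#' @return List of `aligned_sample` objects (variable length).
#' @export
sme_samples <- function(traj, gaze, basics, complexes,
                        lock = c("start", "mid", "end"),
                        spec = sample_spec("sme_start",
                                           agent_filter = "pursued_only")) {
  lock <- match.arg(lock)
  out <- list()
  for (i in which(complexes$kind == "pursuit")) {
    rows <- as.integer(strsplit(complexes$members[i], ",")[[1]])
    smooth <- rows[basics$kind[rows] %in% c("SSM", "FSM")]
    for (r in smooth) {
      f0 <- basics$f_start[r]; f1 <- basics$f_end[r]
      lock_frame <- switch(lock, start = f0, end = f1,
                           mid = f0 + (f1 - f0) %/% 2)
      lock_pos <- c(gaze$x[lock_frame], gaze$y[lock_frame])
      if (anyNA(lock_pos)) next
      ang <- .gaze_direction(gaze, lock_frame)
      if (is.na(ang)) ang <- NULL
      agents <- if (spec$agent_filter == "pursued_only")
        .parse_agents(basics$agents[r]) else NULL
      if (!is.null(agents) && length(agents) == 0) next
      s <- tryCatch(extract_sample(traj, lock_frame, lock_pos, spec,
                                   angle = ang, agents = agents,
                                   offsets = (f0:f1) - lock_frame),
                    error = function(e) NULL)
      if (!is.null(s)) { s$n_agents <- length(agents)
        out[[length(out) + 1L]] <- s }
    }
  }
  out
}
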