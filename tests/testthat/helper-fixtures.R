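# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a DC trial used by several files
fix_trial <- function() fixture("trial_dc", function() generate_trial(seed = 3L))

# a zero-noise group observer on that trial, with its preprocessed gaze
fix_observer <- function() fixture("obs_clean", function() {
  tr <- fix_trial()
  lg <- simulate_observer(tr, observer_params("group", noise_sd = 0,
                                              blink_rate = 0), seed = 5L)
  fg <- preprocess_gaze(lg$raw, n_frames = dim(tr$positions)[2])
  list(trial = tr, gaze = lg, fused = fg,
       events = segment_basic(fg, tr))
})

# hand-built trajectory: agents on straight lines, frame rate 85
toy_trajectory <- function(starts, dirs_deg, speed = 14.5, n_frames = 170,
                           chaser = 1L, chasee = 2L) {
  n <- nrow(starts)
  step <- speed / 85
  pos <- array(NA_real_, dim = c(n, n_frames, 2))
  for (a in seq_len(n)) {
    th <- dirs_deg[a] * pi / 180
    pos[a, , 1] <- starts[a, 1] + step * (seq_len(n_frames) - 1) * cos(th)
    pos[a, , 2] <- starts[a, 2] + step * (seq_len(n_frames) - 1) * sin(th)
  }
  structure(list(positions = pos, chaser_idx = chaser, chasee_idx = chasee,
                 condition = "DC", frame_rate = 85, dir_change_log = NULL,
                 n_bounces = NULL, params = NULL, seed = NA_integer_),
            class = "trial_trajectory")
}

# fused_gaze data frame from a position matrix at 85 Hz
toy_gaze <- function(xy) {
  kin <- derive_kinematics(xy, 85)
  out <- data.frame(frame = seq_len(nrow(xy)),
                    time = (seq_len(nrow(xy)) - 1) / 85,
                    x = xy[, 1], y = xy[, 2],
                    velocity = kin$velocity, acceleration = kin$acceleration,
                    missing = is.na(xy[, 1]))
  class(out) <- c("fused_gaze", "data.frame")
  out
}

# hand-built basic_events row
mk_event <- function(kind, f0, f1, agents = "") {
  data.frame(kind = kind, f_start = f0, f_end = f1,
             t_start = (f0 - 1) / 85, t_end = (f1 - 1) / 85,
             agents = agents)
}

# toy aligned sample from a coordinate array [nt x n_agents x 2]
mk_sample <- function(coords, offsets = NULL) {
  if (is.null(offsets)) offsets <- seq_len(dim(coords)[1]) - 1
  structure(list(coords = coords, agents = seq_len(dim(coords)[2]),
                 angle = 0, lock_frame = 1L, offsets = offsets,
                 condition = "DC"),
            class = "aligned_sample")
}
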