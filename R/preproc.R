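# Raw 500 Hz binocular gaze -> fused, smoothed 85 Hz signal with velocity
# and acceleration. Pipeline order: per-eye Gaussian smoothing, per-eye gap
# interpolation, binocular fusion with a disparity check, linear resampling
# to the display frame rate, kinematic differentiation.

#' Gaussian smoothing of one coordinate axis
#'
#' Discrete Gaussian convolution with a kernel of standard deviation
#' `sd_ms`, truncated at three standard deviations, with reflection padding
#' at the edges. Missing stretches are preserved: each contiguous finite
#' segment is smoothed independently.
#'
#' @param x Numeric series sampled uniformly (NA = missing).
#' @param sd_ms Kernel standard deviation in milliseconds.
#' @param sample_rate Sampling rate in Hz.
#' @return Smoothed series of the same length.
#' @export
smooth_axis <- function(x, sd_ms = 20, sample_rate = 500) {
  sd_s <- sd_ms / 1000 * sample_rate
  half <- max(1L, ceiling(3 * sd_s))
  ker <- exp(-(seq(-half, half))^2 / (2 * sd_s^2))
  ker <- ker / sum(ker)
  out <- x
  for (seg in seq_len(nrow(rs <- .runs_true(!is.na(x))))) {
    i0 <- rs$start[seg]; i1 <- rs$end[seg]
    s <- x[i0:i1]
    n <- length(s)
    if (n == 1) next
    pad <- min(half, n - 1)
    xp <- c(s[(pad + 1):2], s, s[(n - 1):(n - pad)])
    sm <- stats::filter(xp, ker, sides = 2)
    # reflect further if the segment is shorter than the kernel half-width
    if (anyNA(sm[(pad + 1):(pad + n)])) {
      xp <- c(rep(s[1], half), s, rep(s[n], half))
      sm <- stats::filter(xp, ker, sides = 2)
      out[i0:i1] <- sm[(half + 1):(half + n)]
    } else {
      out[i0:i1] <- sm[(pad + 1):(pad + n)]
    }
  }
  out
}

#' Interpolate short missing episodes
#'
#' Missing runs strictly shorter than `max_gap_ms` are filled by linear
#' interpolation between the neighboring finite samples; longer runs (and
#' runs touching the series ends) are left missing.
#'
#' @param x Numeric series (NA = missing).
#' @param max_gap_ms Maximum gap length that is still interpolated (ms).
#' @param sample_rate Sampling rate in Hz.
#' @return Series with short gaps filled.
#' @export
fill_gaps <- function(x, max_gap_ms = 100, sample_rate = 500) {
  gaps <- .runs_true(is.na(x))
  if (nrow(gaps) == 0) return(x)
  for (g in seq_len(nrow(gaps))) {
    i0 <- gaps$start[g]; i1 <- gaps$end[g]
    len_ms <- (i1 - i0 + 1) * 1000 / sample_rate
    if (len_ms >= max_gap_ms) next
    if (i0 == 1 || i1 == length(x)) next
    x[i0:i1] <- x[i0 - 1] + (x[i1 + 1] - x[i0 - 1]) *
      seq_len(i1 - i0 + 1) / (i1 - i0 + 2)
  }
  x
}

#' Fuse the two eyes into one gaze position
#'
#' The gaze is the average of the two eyes where both are present, the
#' single available eye where one is missing, and missing where both are
#' missing or where the inter-eye distance exceeds `max_disparity` degrees
#' (implausible vergence, flagged as tracking error).
#'
#' @param left,right n x 2 matrices of eye positions (deg, NA = missing).
#' @param max_disparity Disparity threshold in degrees.
#' @return n x 2 matrix of fused gaze.
#' @export
fuse_eyes <- function(left, right, max_disparity = 4) {
  l_ok <- !is.na(left[, 1]) & !is.na(left[, 2])
  r_ok <- !is.na(right[, 1]) & !is.na(right[, 2])
  both <- l_ok & r_ok
  disp <- rep(NA_real_, nrow(left))
  disp[both] <- sqrt((left[both, 1] - right[both, 1])^2 +
                     (left[both, 2] - right[both, 2])^2)
  out <- matrix(NA_real_, nrow(left), 2)
  use_both <- both & disp <= max_disparity
  out[use_both, ] <- (left[use_both, , drop = FALSE] +
                      right[use_both, , drop = FALSE]) / 2
  only_l <- l_ok & !r_ok
  out[only_l, ] <- left[only_l, , drop = FALSE]
  only_r <- r_ok & !l_ok
  out[only_r, ] <- right[only_r, , drop = FALSE]
  out
}

# linear resampling of a 500 Hz series onto display frame times; a frame is
# missing if either bracketing source sample is missing
.resample_frames <- function(x, src_rate, frame_times) {
  n <- length(x)
  pos <- frame_times * src_rate          # 0-based source position
  i0 <- pmin(pmax(floor(pos), 0), n - 1L)
  i1 <- pmin(i0 + 1L, n - 1L)
  w <- pos - i0
  out <- (1 - w) * x[i0 + 1L] + w * x[i1 + 1L]
  out[w < 1e-9] <- x[i0 + 1L][w < 1e-9]  # exact hits ignore the right sample
  out
}

#' Velocity and acceleration of the fused gaze
#'
#' Velocity is the magnitude of the central-difference derivative of
#' position times the frame rate (deg/s); acceleration is the central
#' difference of that speed (deg/s^2). Endpoints use one-sided differences.
#'
#' @param xy n x 2 matrix of gaze positions at the display frame rate.
#' @param frame_rate Frame rate in Hz.
#' @return List with `velocity` and `acceleration` vectors.
#' @export
derive_kinematics <- function(xy, frame_rate = 85) {
  n <- nrow(xy)
  cd <- function(z) {
    d <- rep(NA_real_, n)
    if (n >= 3) d[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / 2
    if (n >= 2) { d[1] <- z[2] - z[1]; d[n] <- z[n] - z[n - 1] }
    d * frame_rate
  }
  vx <- cd(xy[, 1]); vy <- cd(xy[, 2])
  vel <- sqrt(vx^2 + vy^2)
  acc <- abs(cd(vel))
  list(velocity = vel, acceleration = acc)
}

#' Preprocess a raw binocular recording into fused 85 Hz gaze
#'
#' Applies, in order: per-eye per-axis Gaussian smoothing (sd 20 ms),
#' per-eye interpolation of missing episodes shorter than 100 ms, binocular
#' fusion with a 4-degree disparity check, linear interpolation to the
#' display frame rate, and kinematic differentiation.
#'
#' @param raw Data frame with columns `time_ms`, `lx`, `ly`, `rx`, `ry`
#'   (NA = missing), regularly sampled.
#' @param n_frames Number of display frames to resample onto.
#' @param frame_rate Display frame rate (Hz).
#' @param sample_rate Recording rate (Hz).
#' @param sd_ms Smoothing kernel sd (ms).
#' @param max_gap_ms Gap-fill limit (ms).
#' @param max_disparity Binocular disparity limit (deg).
#' @return A `fused_gaze` data frame: `frame`, `time`, `x`, `y`, `velocity`,
#'   `acceleration`, `missing`.
#' @export
preprocess_gaze <- function(raw, n_frames = NULL, frame_rate = 85,
                            sample_rate = 500, sd_ms = 20, max_gap_ms = 100,
                            max_disparity = 4) {
  stopifnot(all(c("time_ms", "lx", "ly", "rx", "ry") %in% names(raw)))
  if (is.null(n_frames))
    n_frames <- floor(max(raw$time_ms) / 1000 * frame_rate) + 1L
  eyes <- lapply(c("lx", "ly", "rx", "ry"), function(cl) {
    s <- smooth_axis(raw[[cl]], sd_ms, sample_rate)
    fill_gaps(s, max_gap_ms, sample_rate)
  })
  fused <- fuse_eyes(cbind(eyes[[1]], eyes[[2]]), cbind(eyes[[3]], eyes[[4]]),
                     max_disparity)
  frame_times <- (seq_len(n_frames) - 1) / frame_rate
  x <- .resample_frames(fused[, 1], sample_rate, frame_times)
  y <- .resample_frames(fused[, 2], sample_rate, frame_times)
  kin <- derive_kinematics(cbind(x, y), frame_rate)
  missing <- is.na(x) | is.na(y)
  out <- data.frame(frame = seq_len(n_frames), time = frame_times,
                    x = x, y = y, velocity = kin$velocity,
                    acceleration = kin$acceleration, missing = missing)
  class(out) <- c("fused_gaze", "data.frame")
  out
}

#' Write / read raw gaze samples in a plain-text eye-tracker dialect
#'
#' One line per 2 ms sample: `time_ms lx ly rx ry`, with `.` marking a
#' missing coordinate, mirroring the ASCII sample format of common video
#' eye trackers.
#'
#' @param raw Data frame as accepted by [preprocess_gaze()].
#' @param path File path.
#' @return `write_gaze_asc` returns `path` invisibly; `read_gaze_asc`
#'   returns the data frame.
#' @export
write_gaze_asc <- function(raw, path) {
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.4f", v))
  lines <- paste(sprintf("%.1f", raw$time_ms), fmt(raw$lx), fmt(raw$ly),
                 fmt(raw$rx), fmt(raw$ry), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaze_asc
#' @export
read_gaze_asc <- function(path) {
  m <- utils::read.table(path, sep = "\t", na.strings = ".",
                         col.names = c("time_ms", "lx", "ly", "rx", "ry"))
  m
}

#' Write a fused gaze signal as columnar text
#'
#' @param gaze A `fused_gaze` data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fused_gaze <- function(gaze, path) {
  utils::write.table(format(as.data.frame(gaze), digits = 8),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
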