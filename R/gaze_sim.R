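# Synthetic observer: generates labeled binocular gaze over a chase-display
# trial, alternating exploration (fixations at agent-density maxima joined
# by relocating saccades) and pursuit (a catch-up saccade onto an agent,
# a brief single-agent lock-on, then group tracking at reduced gain with
# interleaved catch-up saccades). Ground-truth event labels are emitted
# alongside, so every downstream stage can be validated against a known
# segmentation.

#' Synthetic observer parameters
#'
#' @param strategy `"group"` (after a brief lock-on, gaze follows the
#'   tracked group at low gain and drifts backwards through it) or
#'   `"single_agent"` (gaze stays locked to one agent at near-unity gain).
#' @param pursuit_gain Gaze speed as a fraction of target speed during
#'   group tracking; defaults to 0.75 for the group strategy and 0.97 for
#'   single-agent tracking. Single-agent lock-on episodes always run at
#'   gain >= 0.97.
#' @param saccade_dur_base_ms,saccade_dur_per_deg Saccade duration model
#'   (ms, ms/deg): duration grows linearly with amplitude.
#' @param fixation_dur_mean,fixation_dur_sd Exploration fixation duration
#'   (ms).
#' @param lockon_dur_mean,lockon_dur_sd Duration (ms) of the single-agent
#'   lock-on episode that opens every pursuit.
#' @param smooth_episode_dur_mean,smooth_episode_dur_sd Duration (ms) of
#'   subsequent smooth-movement episodes.
#' @param p_pursuit Probability of launching pursuit after each exploration
#'   fixation.
#' @param max_episodes Maximum smooth episodes per pursuit.
#' @param p_single_episode For the group strategy, probability that a
#'   non-initial episode is another single-agent lock-on.
#' @param catchup_error Positional error (deg, gaze to tracked agent) that
#'   triggers a catch-up saccade.
#' @param osc_amp,osc_period_ms Amplitude (deg/s) and period (ms) of the
#'   sinusoidal velocity oscillation superposed on smooth movement.
#' @param min_relocation Minimum distance (deg) of an exploration saccade
#'   target from the current gaze (inhibition of return).
#' @param noise_sd Additive white positional noise per eye and axis (deg).
#' @param blink_rate Blinks per minute.
#' @param blink_dur_ms Mean blink duration (ms).
#' @param disparity_inject_deg Optional horizontal disparity (deg) injected
#'   in a few brief windows to exercise disparity-based rejection.
#' @param sample_rate Recording rate (Hz).
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(strategy = c("group", "single_agent"),
                            pursuit_gain = NULL,
                            saccade_dur_base_ms = 20, saccade_dur_per_deg = 2,
                            fixation_dur_mean = 350, fixation_dur_sd = 100,
                            lockon_dur_mean = 250, lockon_dur_sd = 70,
                            smooth_episode_dur_mean = 900,
                            smooth_episode_dur_sd = 250,
                            p_pursuit = 0.5, max_episodes = 5,
                            p_single_episode = 0.1,
                            catchup_error = 2.5,
                            osc_amp = 3, osc_period_ms = 400,
                            min_relocation = 8,
                            noise_sd = 0.1, blink_rate = 4,
                            blink_dur_ms = 150,
                            disparity_inject_deg = 0,
                            sample_rate = 500) {
  strategy <- match.arg(strategy)
  if (is.null(pursuit_gain))
    pursuit_gain <- if (strategy == "group") 0.75 else 0.97
  stopifnot(pursuit_gain > 0, pursuit_gain <= 1.2, noise_sd >= 0)
  p <- mget(setdiff(names(formals()), ""), envir = environment())
  class(p) <- "observer_params"
  p
}

# agent positions interpolated to arbitrary times; n_times x n_agents x 2
.traj_at <- function(traj, times) {
  nf <- dim(traj$positions)[2]
  pos <- traj$positions
  fr <- traj$frame_rate
  p <- pmin(pmax(times * fr, 0), nf - 1L)
  i0 <- floor(p); w <- p - i0
  out <- array(NA_real_, dim = c(length(times), dim(pos)[1], 2))
  for (d in 1:2) {
    a0 <- pos[, i0 + 1L, d, drop = FALSE]
    a1 <- pos[, pmin(i0 + 2L, nf), d, drop = FALSE]
    out[, , d] <- t(a0[, , 1]) * (1 - w) + t(a1[, , 1]) * w
  }
  out
}

#' Saccade target from the agent-density map
#'
#' Position of the maximum of a Gaussian-smoothed agent-density map (kernel
#' sd 2 degrees, evaluated on a half-degree grid over the arena), plus
#' isotropic jitter. Optionally a disk around `exclude_pos` is excluded,
#' modeling inhibition of return during exploration.
#'
#' @param traj A `trial_trajectory`.
#' @param t Time in seconds.
#' @param kernel_sd Density kernel sd (deg).
#' @param grid_step Evaluation grid step (deg).
#' @param jitter_sd Target jitter sd (deg); drawn from the current RNG.
#' @param exclude_pos,exclude_radius Optional exclusion disk.
#' @return Length-2 position (deg).
#' @export
density_saccade_target <- function(traj, t, kernel_sd = 2, grid_step = 0.5,
                                   jitter_sd = 0.3, exclude_pos = NULL,
                                   exclude_radius = 0) {
  ap <- .traj_at(traj, t)[1, , ]
  half <- if (!is.null(traj$params)) traj$params$arena_side / 2 else
    max(abs(traj$positions)) + 0.5
  g <- seq(-half, half, by = grid_step)
  dens <- matrix(0, length(g), length(g))
  for (a in seq_len(nrow(ap)))
    dens <- dens + outer(exp(-(g - ap[a, 1])^2 / (2 * kernel_sd^2)),
                         exp(-(g - ap[a, 2])^2 / (2 * kernel_sd^2)))
  if (!is.null(exclude_pos) && exclude_radius > 0) {
    dd <- sqrt(outer((g - exclude_pos[1])^2, (g - exclude_pos[2])^2, "+"))
    dens[dd < exclude_radius] <- -Inf
  }
  ij <- arrayInd(which.max(dens), dim(dens))
  c(g[ij[1]], g[ij[2]]) + stats::rnorm(2, 0, jitter_sd)
}

# minimum-jerk position profile on [0, 1]
.minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate a synthetic observer over one trial
#'
#' Generates a 500 Hz binocular recording with ground-truth event labels.
#' The observer alternates exploration (fixations at density maxima,
#' relocating saccades) and pursuit (catch-up saccade onto an agent, then
#' smooth movement episodes). During single-agent lock-on episodes the gaze
#' follows one agent's velocity at near-unity gain (fast smooth movement);
#' during group episodes it follows the tracked agent's velocity at the
#' group gain, so the gaze drifts backwards through the group (slow smooth
#' movement) until the accumulated error triggers a catch-up saccade.
#' Saccades follow a minimum-jerk profile with amplitude-dependent
#' duration. Both eyes receive the same signal plus independent white
#' noise; blinks insert simultaneous missing gaps in both eyes.
#'
#' @param traj A `trial_trajectory`.
#' @param params An `observer_params`.
#' @param seed Integer seed.
#' @return A `labeled_gaze` list: `raw` (data frame `time_ms`, `lx`, `ly`,
#'   `rx`, `ry`), `truth_events` (data frame `kind`, `t_start`, `t_end`,
#'   `agents`; kinds `fixation`, `saccade_ES`, `saccade_CS`, `SSM`, `FSM`),
#'   `truth_complex` (`kind` in `exploration`/`pursuit`), `blinks`,
#'   `signal` (noise-free gaze), `params`, `seed`.
#' @export
simulate_observer <- function(traj, params = observer_params(), seed = 1L) {
  sr <- params$sample_rate
  nf <- dim(traj$positions)[2]
  dur_s <- nf / traj$frame_rate
  n <- floor(dur_s * sr)
  times <- (seq_len(n) - 1) / sr
  ap <- .traj_at(traj, times)            # n x agents x 2
  with_seed(as.integer(seed %% 2147480000), {
    gx <- rep(NA_real_, n); gy <- rep(NA_real_, n)
    ev <- list(); cx <- list()
    cur <- 1L
    gaze <- c(0, 0)
    phase <- stats::runif(1, 0, 2 * pi)

    add_ev <- function(kind, i0, i1, agents) {
      ev[[length(ev) + 1L]] <<- data.frame(
        kind = kind, t_start = times[i0], t_end = times[min(i1, n)],
        agents = paste(agents, collapse = ","))
    }
    focus_set <- function(i0, i1) {
      ii <- i0:min(i1, n)
      md <- colMeans(sqrt((ap[ii, , 1, drop = FALSE][, , 1] - gx[ii])^2 +
                          (ap[ii, , 2, drop = FALSE][, , 1] - gy[ii])^2))
      which(md < 4)
    }
    run_saccade <- function(target, kind) {
      amp <- sqrt(sum((target - gaze)^2))
      dur_ms <- max(16, params$saccade_dur_base_ms +
                        params$saccade_dur_per_deg * amp)
      len <- max(4L, round(dur_ms / 1000 * sr))
      if (cur + len > n) len <- n - cur
      if (len < 2) { cur <<- n + 1L; return(invisible(FALSE)) }
      tau <- .minjerk(seq_len(len) / len)
      i0 <- cur
      gx[i0:(i0 + len - 1L)] <<- gaze[1] + (target[1] - gaze[1]) * tau
      gy[i0:(i0 + len - 1L)] <<- gaze[2] + (target[2] - gaze[2]) * tau
      add_ev(kind, i0, i0 + len - 1L, integer(0))
      gaze <<- target
      cur <<- i0 + len
      invisible(TRUE)
    }
    run_fixation <- function(dur_ms) {
      len <- max(2L, round(dur_ms / 1000 * sr))
      if (cur + len - 1L > n) len <- n - cur + 1L
      if (len < 2) { cur <<- n + 1L; return(invisible(integer(0))) }
      i0 <- cur
      gx[i0:(i0 + len - 1L)] <<- gaze[1]
      gy[i0:(i0 + len - 1L)] <<- gaze[2]
      cur <<- i0 + len
      fs <- focus_set(i0, i0 + len - 1L)
      add_ev("fixation", i0, i0 + len - 1L, fs)
      invisible(fs)
    }
    # one smooth episode following `anchor`'s velocity at `gain`; the truth
    # kind is assigned afterwards by the kinematic event definitions (lock
    # on a single agent within 1 degree -> FSM, otherwise SSM)
    run_episode <- function(anchor, gain, dur_ms, ref_at) {
      len <- max(round(0.2 * sr), round(dur_ms / 1000 * sr))
      i0 <- cur
      i <- i0
      while (i < n && i < i0 + len) {
        gx[i] <<- gaze[1]; gy[i] <<- gaze[2]
        osc <- 1 + (params$osc_amp / 14.5) *
          sin(2 * pi * times[i] * 1000 / params$osc_period_ms + phase)
        gaze <<- gaze + (ap[i + 1L, anchor, ] - ap[i, anchor, ]) * gain * osc
        i <- i + 1L
        err <- sqrt(sum((gaze - ref_at(i))^2))
        if (err > params$catchup_error && (i - i0) >= round(0.12 * sr)) break
      }
      if (i > i0) {
        cur <<- i
        # truth kind by the kinematic event definitions applied to the
        # ideal signal: the episode is fast smooth movement if some agent
        # stays within 1 degree over the first 100 ms, within 4 degrees on
        # average overall, and moves in the gaze direction (median angular
        # difference below 25 degrees); otherwise slow smooth movement
        ii <- seq(i0, i - 1L, by = max(1L, round(sr / 85)))
        i100 <- ii[ii < i0 + round(0.1 * sr)]
        fsm_agents <- integer(0)
        # gaze direction as the measurement chain sees it: the recording is
        # smoothed with a 20 ms Gaussian before events are identified, so
        # the direction criterion is evaluated on a smoothed ideal gaze
        sm85 <- function(z) {
          nz <- length(z)
          if (nz < 8) return(z)
          k <- stats::dnorm(-5:5, sd = 1.7); k <- k / sum(k)
          zp <- c(rev(z[2:6]), z, rev(z[(nz - 5):(nz - 1)]))
          as.numeric(stats::filter(zp, k, sides = 2))[6:(5 + nz)]
        }
        gsx <- sm85(gx[ii]); gsy <- sm85(gy[ii])
        g_ang <- .wrap360(atan2(diff(gsy), diff(gsx)) * 180 / pi)
        for (a in seq_len(dim(ap)[2])) {
          d1 <- mean(sqrt((ap[i100, a, 1] - gx[i100])^2 +
                          (ap[i100, a, 2] - gy[i100])^2))
          if (d1 >= 1) next
          d <- mean(sqrt((ap[ii, a, 1] - gx[ii])^2 +
                         (ap[ii, a, 2] - gy[ii])^2))
          if (d >= 4) next
          a_ang <- .wrap360(atan2(diff(ap[ii, a, 2]),
                                  diff(ap[ii, a, 1])) * 180 / pi)
          if (stats::median(.ang_diff(g_ang, a_ang)) < 25)
            fsm_agents <- c(fsm_agents, a)
        }
        kind <- if (length(fsm_agents)) "FSM" else "SSM"
        min_ms <- if (kind == "FSM") 110 else 90
        if ((i - i0) * 1000 / sr >= min_ms) {
          agents <- if (kind == "FSM") fsm_agents else focus_set(i0, i - 1L)
          add_ev(kind, i0, i - 1L, agents)
        }
      }
      invisible(i - i0)
    }

    # ---- behavioral loop ----
    run_fixation(400 + stats::rnorm(1, 0, 50))
    while (cur < n - 10L) {
      if (stats::runif(1) < params$p_pursuit) {
        # pursuit of a candidate in a fresh high-density region (the
        # initiating catch-up saccade targets agent density, like
        # exploration saccades do), together with its nearest neighbor
        # when tracking as a group
        cand <- density_saccade_target(traj, times[cur], exclude_pos = gaze,
                                       exclude_radius = params$min_relocation)
        d <- sqrt((ap[cur, , 1] - cand[1])^2 + (ap[cur, , 2] - cand[2])^2)
        anchor <- which.min(d)
        da <- sqrt((ap[cur, , 1] - ap[cur, anchor, 1])^2 +
                   (ap[cur, , 2] - ap[cur, anchor, 2])^2)
        da[anchor] <- Inf
        # group partner: the nearest agent that is neither so close that
        # the group center falls within the fast-smooth-movement lock
        # radius nor too far to read as a group
        cands <- which(da >= 3 & da <= 6)
        partner_ok <- length(cands) > 0
        partner <- if (partner_ok) cands[which.min(da[cands])] else
          which.min(da)
        px_start <- cur
        # group-strategy pursuits always continue past the initial lock-on
        n_ep <- if (params$strategy == "group" && partner_ok)
          1L + sample.int(params$max_episodes - 1L, 1)
        else sample.int(params$max_episodes, 1)
        members <- anchor
        prev_single <- NA
        for (e in seq_len(n_ep)) {
          if (cur >= n - 10L) break
          single <- params$strategy == "single_agent" || e == 1L ||
            !partner_ok || stats::runif(1) < params$p_single_episode
          # reference point of this episode: the agent itself, or the
          # center of the tracked group
          mk_ref <- function(sgl) function(i) {
            if (sgl) ap[i, anchor, ]
            else (ap[i, anchor, ] + ap[i, partner, ]) / 2
          }
          ref_at <- mk_ref(single)
          err <- sqrt(sum((gaze - ref_at(cur))^2))
          # a tracking-mode switch must be saccade-visible; otherwise stay
          # in the previous mode for this episode
          if (!is.na(prev_single) && !identical(single, prev_single) &&
              err < 1.5) {
            single <- prev_single
            ref_at <- mk_ref(single)
            err <- sqrt(sum((gaze - ref_at(cur))^2))
          }
          gain <- if (single) max(params$pursuit_gain, 0.97) else
            params$pursuit_gain
          # catch-up saccade whenever the reference changed or the gaze
          # fell behind; small corrections continue smoothly instead
          if (err > 1.5 || !identical(single, prev_single)) {
            dur_ms <- max(16, params$saccade_dur_base_ms +
                              params$saccade_dur_per_deg * err)
            land_i <- min(n, cur + round(dur_ms / 1000 * sr))
            if (!run_saccade(ref_at(land_i) + stats::rnorm(2, 0, 0.2),
                             "saccade_CS")) break
          }
          if (cur >= n - 10L) break
          dur <- if (single && params$strategy == "group")
            max(200, stats::rnorm(1, params$lockon_dur_mean,
                                  params$lockon_dur_sd))
          else max(250, stats::rnorm(1, params$smooth_episode_dur_mean,
                                     params$smooth_episode_dur_sd))
          run_episode(anchor, gain, dur, ref_at)
          prev_single <- single
          if (cur > n - 10L) break
          members <- union(members, focus_set(max(1L, cur - 25L), cur))
        }
        cx[[length(cx) + 1L]] <- data.frame(
          kind = "pursuit", t_start = times[px_start],
          t_end = times[min(cur - 1L, n)],
          agents = paste(sort(unique(members)), collapse = ","))
      } else {
        # exploration: relocating saccade to a fresh density maximum,
        # then a fixation there
        ex_start <- cur
        target <- density_saccade_target(traj, times[cur],
                                         exclude_pos = gaze,
                                         exclude_radius = params$min_relocation)
        if (!run_saccade(target, "saccade_ES")) break
        fs <- run_fixation(max(150, stats::rnorm(1, params$fixation_dur_mean,
                                                 params$fixation_dur_sd)))
        cx[[length(cx) + 1L]] <- data.frame(
          kind = "exploration", t_start = times[ex_start],
          t_end = times[min(cur - 1L, n)],
          agents = paste(fs, collapse = ","))
      }
    }
    if (cur <= n) { gx[cur:n] <- gaze[1]; gy[cur:n] <- gaze[2] }
    truth_events <- do.call(rbind, ev)
    truth_complex <- do.call(rbind, cx)
    # taxonomy invariant: pursuit must contain fast smooth movement; a
    # pursuit attempt whose episodes all graded as SSM is exploration
    fsm_ev <- truth_events[truth_events$kind == "FSM", , drop = FALSE]
    for (i in seq_len(nrow(truth_complex))) {
      if (truth_complex$kind[i] != "pursuit") next
      has_fsm <- any(fsm_ev$t_start < truth_complex$t_end[i] &
                     fsm_ev$t_end > truth_complex$t_start[i])
      if (!has_fsm) truth_complex$kind[i] <- "exploration"
    }

    # eyes: common signal + independent noise; optional disparity windows;
    # blinks as simultaneous gaps
    lx <- gx + stats::rnorm(n, 0, params$noise_sd)
    ly <- gy + stats::rnorm(n, 0, params$noise_sd)
    rx <- gx + stats::rnorm(n, 0, params$noise_sd)
    ry <- gy + stats::rnorm(n, 0, params$noise_sd)
    if (params$disparity_inject_deg > 0) {
      for (w in 1:3) {
        i0 <- sample.int(n - 100L, 1)
        ii <- i0:(i0 + 99L)
        lx[ii] <- lx[ii] - params$disparity_inject_deg / 2
        rx[ii] <- rx[ii] + params$disparity_inject_deg / 2
      }
    }
    n_blinks <- stats::rpois(1, params$blink_rate * dur_s / 60)
    blink_iv <- NULL
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, 1, dur_s - 1))
      for (b in starts) {
        len <- max(0.06, stats::rnorm(1, params$blink_dur_ms / 1000, 0.02))
        ii <- which(times >= b & times <= b + len)
        lx[ii] <- NA; ly[ii] <- NA; rx[ii] <- NA; ry[ii] <- NA
        blink_iv <- rbind(blink_iv, c(b, b + len))
      }
    }
    raw <- data.frame(time_ms = times * 1000, lx = lx, ly = ly,
                      rx = rx, ry = ry)
    structure(list(raw = raw, truth_events = truth_events,
                   truth_complex = truth_complex, blinks = blink_iv,
                   signal = data.frame(time = times, x = gx, y = gy),
                   params = params, seed = seed),
              class = "labeled_gaze")
  })
}

#' Write truth labels as a sidecar event file
#'
#' @param gaze A `labeled_gaze`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_events <- function(gaze, path) {
  df <- rbind(cbind(tier = "basic", gaze$truth_events),
              cbind(tier = "complex", gaze$truth_complex))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
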