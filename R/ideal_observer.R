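# Chase-centered ("ideal observer") sampling and analysis: templates built
# directly from the ground-truth chasing pair, representing perfect candidate
# selection against which gaze-derived templates can be compared.

#' Extract chase-centered samples from trial trajectories
#'
#' Draws `n` samples across the given trials (trials weighted by usable
#' duration). For each sample the time lock is chosen uniformly so the whole
#' time window lies inside the trial, the positional lock is set halfway
#' between the chaser's and the chasee's position at the lock, and the
#' sample is rotated to its dominant motion direction.
#'
#' @param trials List of `trial_trajectory` objects.
#' @param n Number of samples.
#' @param spec A `sample_spec`; the default is the +/-400 ms window, all
#'   agents inside the 10 x 10 degree window, rendered as the stimulus rings
#'   (`shape = "ring"`), the rasterization under which the variance
#'   decomposition of these movies is reported.
#' @param seed Integer seed.
#' @return List of `aligned_sample` objects of length `n`.
#' @export
io_samples <- function(trials, n = 5000,
                       spec = sample_spec("io_random", shape = "ring"),
                       seed = 1L) {
  stopifnot(length(trials) >= 1)
  off <- .spec_offsets(spec, trials[[1]]$frame_rate)
  usable <- vapply(trials, function(tr) {
    nf <- dim(tr$positions)[2]
    max(0, (nf - off[length(off)]) - (1 - off[1]) + 1)
  }, numeric(1))
  if (all(usable == 0)) stop("all trials shorter than the sample window")
  with_seed(as.integer(seed %% 2147480000), {
    trial_idx <- sample.int(length(trials), n, replace = TRUE,
                            prob = usable / sum(usable))
    lapply(seq_len(n), function(i) {
      tr <- trials[[trial_idx[i]]]
      nf <- dim(tr$positions)[2]
      lock <- sample((1L - off[1]):(nf - off[length(off)]), 1L)
      lock_pos <- (tr$positions[tr$chaser_idx, lock, ] +
                   tr$positions[tr$chasee_idx, lock, ]) / 2
      keep <- if (spec$agent_filter == "pursued_only")
        c(tr$chaser_idx, tr$chasee_idx) else NULL
      s <- extract_sample(tr, lock, lock_pos, spec, agents = keep)
      s$chaser <- which(s$agents == tr$chaser_idx)
      s$chasee <- which(s$agents == tr$chasee_idx)
      s
    })
  })
}

#' Chase-centered template analysis
#'
#' Runs the template pipeline on chase-centered samples: PCA of the rendered
#' movies, the rail diagram of the first principal component, and a two-line
#' ridge fit. Reports the fitted ridge speeds, the line-offset difference
#' `p1 - p2`, and the inter-ridge distance at the time lock (the two numbers
#' differ when the fitted slopes differ).
#'
#' @param samples List of `aligned_sample` objects from [io_samples()].
#' @param k Number of principal components to keep.
#' @param spec The `sample_spec` used for extraction (rasterization comes
#'   from here).
#' @return List with `pca` (see [pca_templates()]), `rail` (PC1 rail
#'   diagram), `fit` (two-line `line_fit`), `ridge_speeds` (descending
#'   absolute slopes, deg/s), `line_offset_difference` (deg),
#'   `inter_ridge_distance_at_lock` (deg) and `pc1_var_pct`.
#' @export
io_analysis <- function(samples, k = 5,
                        spec = sample_spec("io_random", shape = "ring")) {
  pca <- pca_templates(samples, k = k, half_width = spec$half_width,
                       pixel_size = spec$pixel_size, blob_sd = spec$blob_sd,
                       shape = spec$shape, ring_radius = spec$ring_radius,
                       ring_sd = spec$ring_sd)
  rail <- rail_diagram(pca$movies[[1]])
  fit <- fit_lines(rail, n_lines = 2)
  ln <- fit$lines
  t_lock <- -attr(rail, "times")[1]      # seconds from window start to lock
  x_at_lock <- ln$p + ln$v * t_lock
  list(pca = pca, rail = rail, fit = fit,
       ridge_speeds = sort(abs(ln$v), decreasing = TRUE),
       line_offset_difference = ln$p[1] - ln$p[2],
       inter_ridge_distance_at_lock = abs(x_at_lock[1] - x_at_lock[2]),
       pc1_var_pct = 100 * pca$var_frac[1])
}
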