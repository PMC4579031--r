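# Spatiotemporal template engine: aligned samples around gaze events,
# rendered template movies, PCA by eigendecomposition, kernel-regression
# average templates, rail diagrams and ridge-line fitting.

#' Specification of a spatiotemporal sample window
#'
#' Describes how samples are cut out of a trial: the time window relative to
#' the lock event, the square spatial window, the rasterization used when
#' rendering, and how samples are rotationally aligned.
#'
#' @param lock_kind One of `"detection"`, `"saccade_onset"`, `"sme_start"`,
#'   `"sme_mid"`, `"sme_end"`, `"io_random"`.
#' @param t_lo,t_hi Time window in seconds relative to the lock. Frames are
#'   taken at the display frame rate; the window `[t_lo, t_hi)` of length
#'   0.8 s yields 68 frames at 85 Hz.
#' @param half_width Spatial half-width in degrees (10 x 10 degree window by
#'   default).
#' @param pixel_size Pixel size in degrees for rendering.
#' @param shape Agent footprint used when rendering: `"gaussian"` deposits an
#'   isotropic Gaussian blob of sd `blob_sd` (a smooth surrogate that makes
#'   rendering and kernel regression exactly equivalent); `"ring"` deposits
#'   the stimulus ring itself (radius `ring_radius`, Gaussian radial
#'   cross-section of sd `ring_sd`).
#' @param blob_sd Standard deviation (deg) of the Gaussian blob.
#' @param ring_radius Ring radius in degrees (the stimulus rings had a
#'   1-degree diameter).
#' @param ring_sd Radial cross-section sd of the ring stroke (deg).
#' @param rotation_source `"dominant_direction"` (mode of the weighted radial
#'   histogram of agent motion) or `"gaze_direction"`.
#' @param agent_filter `"all"` or `"pursued_only"`.
#' @return A list of class `sample_spec`.
#' @export
sample_spec <- function(lock_kind = c("io_random", "detection", "saccade_onset",
                                      "sme_start", "sme_mid", "sme_end"),
                        t_lo = -0.4, t_hi = 0.4, half_width = 5,
                        pixel_size = 0.25, shape = c("gaussian", "ring"),
                        blob_sd = 0.5, ring_radius = 0.5, ring_sd = 0.125,
                        rotation_source = c("dominant_direction", "gaze_direction"),
                        agent_filter = c("all", "pursued_only")) {
  lock_kind <- match.arg(lock_kind)
  shape <- match.arg(shape)
  rotation_source <- match.arg(rotation_source)
  agent_filter <- match.arg(agent_filter)
  stopifnot(t_lo < t_hi, half_width > 0, pixel_size > 0, blob_sd > 0,
            ring_radius > 0, ring_sd > 0)
  structure(list(lock_kind = lock_kind, t_lo = t_lo, t_hi = t_hi,
                 half_width = half_width, pixel_size = pixel_size,
                 shape = shape, blob_sd = blob_sd, ring_radius = ring_radius,
                 ring_sd = ring_sd, rotation_source = rotation_source,
                 agent_filter = agent_filter),
            class = "sample_spec")
}

# frame offsets (relative to the lock frame) covering [t_lo, t_hi)
.spec_offsets <- function(spec, frame_rate = 85) {
  n <- round((spec$t_hi - spec$t_lo) * frame_rate)
  seq(round(spec$t_lo * frame_rate), length.out = n)
}

#' Dominant motion direction near a positional lock
#'
#' The mode of a radial histogram of per-frame, per-agent motion directions
#' within a time window, each contribution weighted by the agent's distance
#' `d` to the positional lock through the circular polynomial window
#' `w(d) = max(0, 1 - (d / radius)^2)`. The modal 10-degree bin is refined by
#' the weighted circular mean of the contributions falling inside it.
#'
#' @param traj A `trial_trajectory`.
#' @param frames Integer vector of frame indices in the window.
#' @param lock_pos Length-2 position of the lock (deg).
#' @param radius Support radius of the weighting window (deg).
#' @param n_bins Number of histogram bins.
#' @return Angle in degrees in `[0, 360)`.
#' @export
dominant_direction <- function(traj, frames, lock_pos, radius = 5, n_bins = 36) {
  pos <- traj$positions
  f <- frames[frames >= 1 & frames < dim(pos)[2]]
  if (length(f) < 1) stop("window outside the trial")
  dx <- pos[, f + 1L, 1, drop = FALSE] - pos[, f, 1, drop = FALSE]
  dy <- pos[, f + 1L, 2, drop = FALSE] - pos[, f, 2, drop = FALSE]
  ang <- .wrap360(atan2(dy, dx) * 180 / pi)
  d <- sqrt((pos[, f, 1] - lock_pos[1])^2 + (pos[, f, 2] - lock_pos[2])^2)
  w <- pmax(0, 1 - (d / radius)^2)
  if (sum(w) == 0) stop("no agents within the weighting window")
  bin <- pmin(floor(ang / (360 / n_bins)), n_bins - 1L)
  h <- vapply(0:(n_bins - 1L), function(b) sum(w[bin == b]), numeric(1))
  mb <- which.max(h) - 1L
  sel <- bin == mb & w > 0
  .circ_mean(ang[sel], w[sel])
}

#' Extract one aligned spatiotemporal sample
#'
#' Translates agent coordinates so the lock is at the origin and rotates them
#' so the alignment direction maps onto the positive x axis. The rotation is
#' a pure isometry; spatial cropping happens at rendering time.
#'
#' @param traj A `trial_trajectory`.
#' @param lock_frame Frame index of the time lock.
#' @param lock_pos Length-2 lock position (deg).
#' @param spec A `sample_spec`.
#' @param angle Alignment angle in degrees; if `NULL`, the dominant motion
#'   direction around the lock is used.
#' @param agents Agent indices to keep (default all).
#' @param offsets Explicit frame offsets relative to the lock (overrides the
#'   window in `spec`; used for variable-length episode samples).
#' @return An `aligned_sample`: list with `coords`
#'   (`n_frames x n_agents x 2`), `agents`, `angle`, `lock_frame`,
#'   `offsets` and `condition`.
#' @export
extract_sample <- function(traj, lock_frame, lock_pos, spec, angle = NULL,
                           agents = NULL, offsets = NULL) {
  off <- if (is.null(offsets)) .spec_offsets(spec, traj$frame_rate)
         else as.integer(offsets)
  frames <- lock_frame + off
  nf <- dim(traj$positions)[2]
  if (frames[1] < 1 || frames[length(frames)] > nf)
    stop("sample window exceeds trial bounds")
  if (is.null(angle))
    angle <- dominant_direction(traj, frames, lock_pos)
  if (is.null(agents)) agents <- seq_len(dim(traj$positions)[1])
  th <- -angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- traj$positions[agents, frames, , drop = FALSE]
  xy[, , 1] <- xy[, , 1] - lock_pos[1]
  xy[, , 2] <- xy[, , 2] - lock_pos[2]
  coords <- array(NA_real_, dim = c(length(frames), length(agents), 2))
  coords[, , 1] <- t(xy[, , 1] * R[1, 1] + xy[, , 2] * R[1, 2])
  coords[, , 2] <- t(xy[, , 1] * R[2, 1] + xy[, , 2] * R[2, 2])
  structure(list(coords = coords, agents = agents, angle = angle,
                 lock_frame = lock_frame, offsets = off,
                 condition = traj$condition),
            class = "aligned_sample")
}

# pixel centers for a window of half-width hw and pixel size ps
.pixel_centers <- function(hw, ps) {
  n <- round(2 * hw / ps)
  -hw + (seq_len(n) - 0.5) * ps
}

# deposit one frame's agent coordinates into `frame` (npix x npix matrix,
# x = rows, y = columns), evaluated at pixel centers, truncated at 3 sd;
# peak amplitude 1 per agent. shape "gaussian": isotropic blob of sd `sd`;
# shape "ring": annulus of radius `ring_radius` with radial Gaussian
# cross-section of sd `sd`.
.deposit_frame <- function(frame, xy, hw, ps, sd, shape = "gaussian",
                           ring_radius = 0.5) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  npix <- nrow(frame)
  r <- 3 * sd + if (shape == "ring") ring_radius else 0
  for (a in seq_len(nrow(xy))) {
    x <- xy[a, 1]; y <- xy[a, 2]
    if (is.na(x) || abs(x) > hw + r || abs(y) > hw + r) next
    ilo <- max(1L, floor((x - r + hw) / ps) + 1L)
    ihi <- min(npix, ceiling((x + r + hw) / ps))
    jlo <- max(1L, floor((y - r + hw) / ps) + 1L)
    jhi <- min(npix, ceiling((y + r + hw) / ps))
    if (ilo > ihi || jlo > jhi) next
    cx <- -hw + (ilo:ihi - 0.5) * ps
    cy <- -hw + (jlo:jhi - 0.5) * ps
    if (shape == "gaussian") {
      gx <- exp(-(cx - x)^2 / (2 * sd^2))
      gy <- exp(-(cy - y)^2 / (2 * sd^2))
      gx[abs(cx - x) > r] <- 0
      gy[abs(cy - y) > r] <- 0
      frame[ilo:ihi, jlo:jhi] <- frame[ilo:ihi, jlo:jhi] + outer(gx, gy)
    } else {
      dd <- sqrt(outer((cx - x)^2, (cy - y)^2, "+"))
      g <- exp(-(dd - ring_radius)^2 / (2 * sd^2))
      g[abs(dd - ring_radius) > 3 * sd] <- 0
      frame[ilo:ihi, jlo:jhi] <- frame[ilo:ihi, jlo:jhi] + g
    }
  }
  frame
}

# resolve rendering arguments from a sample_spec
.render_args <- function(spec) {
  list(shape = spec$shape,
       sd = if (spec$shape == "gaussian") spec$blob_sd else spec$ring_sd,
       ring_radius = spec$ring_radius)
}

#' Render aligned samples and average them into a template movie
#'
#' Each agent is deposited per frame as an isotropic Gaussian blob (a smooth
#' stand-in for the 1-degree stimulus ring), and the rendered movies are
#' averaged. For variable-length sample sets, each frame of the template
#' averages only the samples that extend that far.
#'
#' @param samples List of `aligned_sample` objects.
#' @param half_width,pixel_size,blob_sd Rasterization parameters (deg).
#' @param shape `"gaussian"` or `"ring"` (see [sample_spec()]).
#' @param ring_radius,ring_sd Ring geometry when `shape = "ring"`.
#' @return A `template_movie`: array `npix x npix x T` (x, y, time) with
#'   attributes `pixel_size`, `half_width`, `times` and `n_contrib`.
#' @export
render_movie <- function(samples, half_width = 5, pixel_size = 0.25,
                         blob_sd = 0.5, shape = c("gaussian", "ring"),
                         ring_radius = 0.5, ring_sd = 0.125) {
  shape <- match.arg(shape)
  sd <- if (shape == "gaussian") blob_sd else ring_sd
  stopifnot(length(samples) >= 1)
  # global frame axis: samples are positioned by their lock-relative frame
  # offsets, so variable-length and differently locked samples line up
  off0 <- vapply(samples, function(s) s$offsets[1], numeric(1))
  off1 <- vapply(samples, function(s) s$offsets[length(s$offsets)], numeric(1))
  o_min <- min(off0); o_max <- max(off1)
  nt <- as.integer(o_max - o_min + 1)
  npix <- round(2 * half_width / pixel_size)
  acc <- array(0, dim = c(npix, npix, nt))
  counts <- integer(nt)
  for (s in samples) {
    base <- as.integer(s$offsets[1] - o_min)
    for (t in seq_len(dim(s$coords)[1])) {
      tt <- base + t
      acc[, , tt] <- .deposit_frame(acc[, , tt], s$coords[t, , , drop = TRUE],
                                    half_width, pixel_size, sd, shape,
                                    ring_radius)
      counts[tt] <- counts[tt] + 1L
    }
  }
  for (t in which(counts > 0)) acc[, , t] <- acc[, , t] / counts[t]
  structure(acc, pixel_size = pixel_size, half_width = half_width,
            times = (o_min + seq_len(nt) - 1) / 85, n_contrib = counts,
            class = "template_movie")
}

#' Average template by kernel regression on sample coordinates
#'
#' Computes the kernel-weighted mean occupancy per space-time pixel directly
#' from the agent coordinates (Nadaraya-Watson style, Gaussian spatial kernel
#' truncated at 3 sd), normalized per frame by the number of contributing
#' samples. For equal-length samples and `kernel_sd = blob_sd` this equals
#' rendering every sample and averaging.
#'
#' @param samples List of `aligned_sample` objects (lengths may differ).
#' @param half_width,pixel_size Rasterization parameters (deg).
#' @param kernel_sd Gaussian kernel standard deviation (deg).
#' @return A `template_movie`.
#' @export
npr_template <- function(samples, half_width = 5, pixel_size = 0.25,
                         kernel_sd = 0.5) {
  render_movie(samples, half_width, pixel_size, kernel_sd)
}

#' Principal-component template movies
#'
#' Renders every sample and computes PCA by eigendecomposition, working on
#' the n x n Gram matrix so the pixel dimension is never squared. By
#' default the decomposition is of the raw second moment (no mean
#' subtraction), so that for a unimodal sample distribution the first
#' component recovers the average template and subsequent components act as
#' shift/modulation patterns; `center = TRUE` gives the covariance
#' (mean-centered) decomposition instead, via double-centering of the Gram
#' matrix. Requires equal-length samples. Eigen-movies are unit-norm and
#' oriented so the pixel with the largest absolute loading is positive.
#'
#' @param samples List of `aligned_sample` objects of equal length.
#' @param k Number of component movies to return.
#' @param half_width,pixel_size,blob_sd Rasterization parameters (deg).
#' @param shape `"gaussian"` or `"ring"` (see [sample_spec()]).
#' @param ring_radius,ring_sd Ring geometry when `shape = "ring"`.
#' @param center Subtract the mean template before decomposing?
#' @return List with `movies` (list of `k` eigen-movie arrays), `var_frac`
#'   (all positive eigenvalue fractions, descending), `values`
#'   (eigenvalues), `scores` (n x k matrix of sample scores), `mean`
#'   (the average template movie) and `center`.
#' @export
pca_templates <- function(samples, k = 5, half_width = 5, pixel_size = 0.25,
                          blob_sd = 0.5, shape = c("gaussian", "ring"),
                          ring_radius = 0.5, ring_sd = 0.125, center = FALSE) {
  shape <- match.arg(shape)
  sd <- if (shape == "gaussian") blob_sd else ring_sd
  n <- length(samples)
  if (n < 2) stop("PCA needs at least two samples")
  nts <- vapply(samples, function(s) dim(s$coords)[1], integer(1))
  if (length(unique(nts)) != 1) stop("PCA requires equal-length samples")
  nt <- nts[1]
  npix <- round(2 * half_width / pixel_size)
  D <- npix * npix * nt
  X <- matrix(0, n, D)
  mov <- array(0, dim = c(npix, npix, nt))
  for (i in seq_len(n)) {
    m <- mov
    for (t in seq_len(nt))
      m[, , t] <- .deposit_frame(m[, , t], samples[[i]]$coords[t, , , drop = TRUE],
                                 half_width, pixel_size, sd, shape, ring_radius)
    X[i, ] <- m
  }
  G <- tcrossprod(X)
  if (center) {
    rm_ <- rowMeans(G); gm <- mean(G)
    G <- G - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  }
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  values <- e$values[pos]
  var_frac <- values / sum(values)
  k <- min(k, length(values))
  movies <- vector("list", k)
  scores <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    u <- e$vectors[, j]
    if (center) u <- u - mean(u)
    v <- drop(crossprod(X, u)) / sqrt(values[j])
    if (abs(min(v)) > abs(max(v))) { v <- -v; u <- -u }
    mj <- array(v, dim = c(npix, npix, nt))
    movies[[j]] <- structure(mj, pixel_size = pixel_size,
                             half_width = half_width,
                             times = (samples[[1]]$offsets[1] + seq_len(nt) - 1) / 85,
                             class = "template_movie")
    scores[, j] <- u * sqrt(values[j])
  }
  mean_movie <- structure(array(colMeans(X), dim = c(npix, npix, nt)),
                          pixel_size = pixel_size, half_width = half_width,
                          times = (samples[[1]]$offsets[1] + seq_len(nt) - 1) / 85,
                          class = "template_movie")
  list(movies = movies, var_frac = var_frac, values = values,
       scores = scores, mean = mean_movie, center = center)
}

#' Rail diagram of a template movie
#'
#' Collapses a template movie onto the alignment axis: for each time frame,
#' pixel values are averaged over the band of rows within `band / 2` degrees
#' of the axis, giving a time x on-axis-position matrix in which constant
#' agent motion appears as a line whose slope is the agent's velocity and a
#' chase appears as two parallel lines.
#'
#' @param movie A `template_movie`.
#' @param band Band width (deg) centered on the alignment axis.
#' @return A `rail_diagram`: matrix `T x X` with attributes `times` (s) and
#'   `xs` (deg).
#' @export
rail_diagram <- function(movie, band = 0.3) {
  hw <- attr(movie, "half_width"); ps <- attr(movie, "pixel_size")
  cy <- .pixel_centers(hw, ps)
  rows <- which(abs(cy) <= band / 2 + 1e-9)
  if (length(rows) == 0) stop("no pixel row inside the band; pixel size too coarse")
  nt <- dim(movie)[3]
  rail <- t(vapply(seq_len(nt), function(t)
    rowMeans(matrix(movie[, rows, t], ncol = length(rows))),
    numeric(dim(movie)[1])))
  times <- attr(movie, "times")
  if (is.null(times)) times <- (seq_len(nt) - 1) / 85
  structure(rail, times = times, xs = cy, class = "rail_diagram")
}

# unimodal ridge pattern summed over lines; h is the printed line-distance
# expression (denominator 1 + v^2) or the geometric point-line distance
# (denominator sqrt(1 + v^2)); the cube is taken on |h/s| so the profile is
# unimodal and bounded by [0, 1]
.line_pattern <- function(tt, xx, par, n_lines, denominator) {
  pat <- 0
  for (l in seq_len(n_lines)) {
    p <- par[3 * l - 2]; v <- par[3 * l - 1]; s <- exp(par[3 * l])
    den <- if (denominator == "printed") 1 + v^2 else sqrt(1 + v^2)
    h <- (p + v * tt - xx) / den
    pat <- pat + pmax(0, 1 - abs(h / s)^3)
  }
  pat
}

#' Fit ridge lines to a rail diagram
#'
#' Maximizes, with the Nelder-Mead simplex, the Pearson correlation between
#' the rail diagram (normalized to `[0, 1]`) and a pattern obtained by
#' summing one or two unimodal ridge profiles
#' `max(0, 1 - |h(x, t) / s|^3)`, where
#' `h(x, t) = (p + v t - x) / (1 + v^2)` is the signed line offset, `p` the
#' offset (deg) at the start of the time window, `v` the slope (deg/s) and
#' `s` the band-width parameter. Multi-start initialization from a
#' regression through the per-frame maxima plus lateral offsets.
#'
#' @param rail A `rail_diagram`.
#' @param n_lines 1 or 2.
#' @param init Optional list of numeric start vectors
#'   `c(p1, v1, s1, p2, v2, s2)`.
#' @param denominator `"printed"` uses the `1 + v^2` denominator as reported;
#'   `"geometric"` uses `sqrt(1 + v^2)` (the true point-line distance). The
#'   two are reparametrizations of each other in `s`, so fitted `p` and `v`
#'   agree; only the scale of `s` differs.
#' @return A `line_fit` list: `lines` (data.frame with `p`, `v`, `s`),
#'   `correlation`, `n_lines`, `denominator`.
#' @export
fit_lines <- function(rail, n_lines = 1, init = NULL,
                      denominator = c("printed", "geometric")) {
  denominator <- match.arg(denominator)
  stopifnot(n_lines %in% c(1, 2))
  times <- attr(rail, "times"); xs <- attr(rail, "xs")
  r <- (rail - min(rail)) / (max(rail) - min(rail))
  if (!is.finite(sum(r)) || stats::sd(r) == 0) stop("rail diagram is flat")
  t0 <- times - times[1]
  tt <- matrix(t0, nrow(rail), ncol(rail))
  xx <- matrix(xs, nrow(rail), ncol(rail), byrow = TRUE)
  rv <- as.vector(r)
  # optimization always runs in the geometric parametrization of s (the
  # printed 1 + v^2 denominator couples band width to slope so strongly
  # that the simplex stalls); the two conventions describe identical
  # patterns, so s is converted on input and output
  obj <- function(par) {
    pat <- as.vector(.line_pattern(tt, xx, par, n_lines, "geometric"))
    if (stats::sd(pat) == 0) return(1)
    -stats::cor(rv, pat)
  }
  # initialization from the per-frame argmax ridge of a laterally smoothed
  # copy (robust against sub-structure such as the twin maxima a thin ring
  # leaves in the band average)
  ker <- stats::dnorm(seq(-3, 3, length.out = 13))
  ker <- ker / sum(ker)
  rs <- t(apply(r, 1, function(row)
    stats::filter(c(rev(row[1:6]), row, rev(row[(length(row) - 5):length(row)])),
                  ker)[7:(6 + length(row))]))
  ridge_line <- function(rr) {
    amax <- xs[apply(rr, 1, which.max)]
    w <- apply(rr, 1, max); w <- w - min(w) + 1e-9
    cf <- stats::coef(stats::lm(amax ~ t0, weights = w))
    c(unname(cf[1]), unname(cf[2]))
  }
  pv0 <- ridge_line(rs)
  p0 <- pv0[1]; v0 <- pv0[2]
  den0 <- function(v) sqrt(1 + v^2)
  widths <- c(0.75, 1.6)
  ls0 <- log(widths[1] / max(den0(v0), 1))
  starts <- list()
  if (n_lines == 1) {
    for (w0 in widths) for (dp in c(0, -1, 1))
      starts <- c(starts, list(c(p0 + dp, v0, log(w0 / max(den0(v0), 1)))))
  } else {
    # second-ridge start: mask the first ridge and regress the residual maxima
    mask <- abs(matrix(p0 + v0 * t0, nrow(r), ncol(r)) - xx) < 1.25
    r2 <- rs; r2[mask] <- min(rs)
    pv1 <- ridge_line(r2)
    for (w0 in widths) {
      lw0 <- log(w0 / max(den0(v0), 1))
      lw1 <- log(w0 / max(den0(pv1[2]), 1))
      starts <- c(starts, list(c(p0, v0, lw0, pv1[1], pv1[2], lw1),
                               c(p0, v0, lw0, pv1[1], v0, lw0)))
      for (dp in c(1, 2, 3, 4))
        starts <- c(starts,
                    list(c(p0 + dp / 2, v0, lw0, p0 - dp / 2, v0, lw0),
                         c(p0 + dp, v0, lw0, p0, v0, lw0),
                         c(p0, v0, lw0, p0 - dp, v0, lw0)))
    }
  }
  if (n_lines == 2) {
    # sequential strategy: fit one line, mask its band, fit the second on
    # the remainder, then refine jointly; robust when the two ridges have
    # very different strengths
    f1 <- fit_lines(rail, 1, denominator = "geometric")
    l1 <- f1$lines
    bw <- max(1, l1$s * den0(l1$v))
    m2 <- abs(matrix(l1$p + l1$v * t0, nrow(r), ncol(r)) - xx) < bw
    r2 <- rail
    r2[m2] <- min(rail)
    f2 <- tryCatch(fit_lines(r2, 1, denominator = "geometric"),
                   error = function(e) NULL)
    if (!is.null(f2))
      starts <- c(list(c(l1$p, l1$v, log(l1$s), f2$lines$p, f2$lines$v,
                         log(f2$lines$s))), starts)
  }
  if (!is.null(init))
    starts <- c(lapply(init, function(s) {
      si <- seq(3, length(s), by = 3)
      if (denominator == "printed")   # convert s to the geometric scale
        s[si] <- s[si] * sqrt(1 + s[si - 1]^2)
      s[si] <- log(s[si])
      s
    }), starts)
  # stage 1: optimize every start against the laterally smoothed rail,
  # whose basin of attraction is wide (sub-structure such as the ring
  # cross-section is blurred out); stage 2: refine the best candidates on
  # the raw rail
  rsv <- as.vector((rs - min(rs)) / (max(rs) - min(rs)))
  obj_s <- function(par) {
    pat <- as.vector(.line_pattern(tt, xx, par, n_lines, "geometric"))
    if (stats::sd(pat) == 0) return(1)
    -stats::cor(rsv, pat)
  }
  stage1 <- lapply(starts, function(st)
    stats::optim(st, obj_s, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-8)))
  ord <- order(vapply(stage1, `[[`, numeric(1), "value"))
  cands <- c(lapply(stage1[ord[seq_len(min(3, length(ord)))]], `[[`, "par"),
             starts[1])
  best <- NULL
  for (st in cands) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         abs(fit$par[1]) < abs(best$par[1])))
      best <- fit
  }
  par <- best$par
  lines <- data.frame(p = par[seq(1, 3 * n_lines, by = 3)],
                      v = par[seq(2, 3 * n_lines, by = 3)],
                      s = exp(par[seq(3, 3 * n_lines, by = 3)]))
  if (denominator == "printed")
    lines$s <- lines$s / sqrt(1 + lines$v^2)
  lines <- lines[order(-lines$p), , drop = FALSE]
  rownames(lines) <- NULL
  structure(list(lines = lines, correlation = -best$value,
                 n_lines = n_lines, denominator = denominator,
                 t0 = times[1]),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("ridge-line fit (%d line%s, correlation %.3f)\n", x$n_lines,
              if (x$n_lines > 1) "s" else "", x$correlation))
  print(round(x$lines, 3))
  invisible(x)
}
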