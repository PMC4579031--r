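test_that("dominant direction finds the weighted modal motion direction", {
  tt <- toy_trajectory(rbind(c(0, 0), c(9, 9)), c(0, 90), n_frames = 80)
  expect_lt(abs(dominant_direction(tt, 1:60, c(0, 0))), 1)
  # agent beyond the 5-degree window has zero weight
  tt <- toy_trajectory(rbind(c(0, 0), c(6, 0)), c(0, 90), n_frames = 80)
  expect_lt(abs(dominant_direction(tt, 1:20, c(0, 0))), 1)
  expect_error(dominant_direction(tt, 1:20, c(50, 50)), "no agents")
  # random configurations against a literal weighted-histogram oracle
  withr::local_seed(10)
  for (rep in 1:10) {
    n <- 5
    tt <- toy_trajectory(cbind(runif(n, -4, 4), runif(n, -4, 4)),
                         runif(n, 0, 360), n_frames = 40)
    got <- dominant_direction(tt, 1:30, c(0, 0))
    ang <- c(); w <- c()
    for (a in 1:n) for (f in 1:30) {
      dx <- tt$positions[a, f + 1, 1] - tt$positions[a, f, 1]
      dy <- tt$positions[a, f + 1, 2] - tt$positions[a, f, 2]
      d <- sqrt(sum(tt$positions[a, f, ]^2))
      ang <- c(ang, (atan2(dy, dx) * 180 / pi) %% 360)
      w <- c(w, max(0, 1 - (d / 5)^2))
    }
    h <- vapply(0:35, function(b) sum(w[floor(ang / 10) == b]), numeric(1))
    mb <- which.max(h) - 1
    sel <- floor(ang / 10) == mb & w > 0
    sw <- sum(w[sel] * sin(ang[sel] * pi / 180))
    cw <- sum(w[sel] * cos(ang[sel] * pi / 180))
    oracle <- (atan2(sw, cw) * 180 / pi) %% 360
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("sample extraction translates, rotates and preserves distances", {
  tt <- toy_trajectory(rbind(c(0, 0), c(2, 1)), c(0, 0), n_frames = 170)
  spec <- sample_spec("io_random")
  s <- extract_sample(tt, 40, c(tt$positions[1, 40, 1], 0), spec, angle = 0)
  # agent 1 moves along the alignment axis through the lock
  expect_equal(s$coords[, 1, 2], rep(0, 68), tolerance = 1e-9)
  expect_equal(diff(s$coords[, 1, 1]), rep(14.5 / 85, 67), tolerance = 1e-9)
  # pure rotation: pairwise distances preserved for any angle
  s2 <- extract_sample(tt, 40, c(1, 1), spec, angle = 137)
  d0 <- sqrt((tt$positions[1, 40, 1] - tt$positions[2, 40, 1])^2 +
             (tt$positions[1, 40, 2] - tt$positions[2, 40, 2])^2)
  d1 <- sqrt(sum((s2$coords[35, 1, ] - s2$coords[35, 2, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  # window bound checking
  expect_error(extract_sample(tt, 10, c(0, 0), spec), "exceeds")
})

test_that("alignment makes templates invariant to global rotation", {
  tr <- fix_trial()
  spec <- sample_spec("io_random")
  rot <- function(tr, th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    p <- tr$positions
    for (a in seq_len(dim(p)[1])) p[a, , ] <- p[a, , ] %*% t(R)
    tr$positions <- p
    tr
  }
  trR <- rot(tr, 70 * pi / 180)
  lock <- (tr$positions[1, 500, ] + tr$positions[2, 500, ]) / 2
  lockR <- (trR$positions[1, 500, ] + trR$positions[2, 500, ]) / 2
  s1 <- extract_sample(tr, 500, lock, spec)
  s2 <- extract_sample(trR, 500, lockR, spec)
  expect_equal(s1$coords, s2$coords, tolerance = 1e-6)
})

test_that("rendering matches a literal per-pixel oracle and kernel regression", {
  withr::local_seed(11)
  samples <- lapply(1:6, function(i)
    mk_sample(array(runif(3 * 2 * 2, -2, 2), dim = c(3, 2, 2))))
  mov <- render_movie(samples, half_width = 3, pixel_size = 0.5, blob_sd = 0.5)
  # quadruple-loop oracle (separable kernel, per-axis 3 sd truncation)
  cx <- seq(-2.75, 2.75, by = 0.5)
  for (t in 1:3) for (ix in seq_along(cx)) for (iy in seq_along(cx)) {
    v <- 0
    for (s in samples) for (a in 1:2) {
      dx <- abs(cx[ix] - s$coords[t, a, 1])
      dy <- abs(cx[iy] - s$coords[t, a, 2])
      if (dx <= 1.5 && dy <= 1.5)
        v <- v + exp(-(dx^2 + dy^2) / (2 * 0.25))
    }
    expect_equal(mov[ix, iy, t], v / 6, tolerance = 1e-6)
  }
  # kernel regression route identical for equal-length samples
  npr <- npr_template(samples, half_width = 3, pixel_size = 0.5,
                      kernel_sd = 0.5)
  expect_equal(as.numeric(npr), as.numeric(mov), tolerance = 1e-12)
})

test_that("variable-length samples contribute only where they extend", {
  long <- mk_sample(array(c(rep(1, 6), rep(0, 6)), dim = c(6, 1, 2)))
  short <- mk_sample(array(c(rep(-1, 3), rep(0, 3)), dim = c(3, 1, 2)))
  mov <- npr_template(list(long, short), half_width = 3, pixel_size = 0.5)
  expect_equal(attr(mov, "n_contrib"), c(2L, 2L, 2L, 1L, 1L, 1L))
  # later frames equal the long sample's own rendering
  solo <- render_movie(list(long), half_width = 3, pixel_size = 0.5)
  expect_equal(mov[, , 5], solo[, , 5], tolerance = 1e-12)
})

test_that("PCA by Gram eigendecomposition matches a dense oracle", {
  withr::local_seed(12)
  samples <- lapply(1:20, function(i)
    mk_sample(array(runif(5 * 2 * 2, -2, 2), dim = c(5, 2, 2))))
  p <- pca_templates(samples, k = 4, half_width = 2, pixel_size = 0.5,
                     blob_sd = 0.4)
  # dense second-moment oracle
  X <- t(vapply(samples, function(s)
    as.numeric(render_movie(list(s), half_width = 2, pixel_size = 0.5,
                            blob_sd = 0.4)), numeric(8 * 8 * 5)))
  M <- crossprod(X)
  e <- eigen(M, symmetric = TRUE)
  expect_equal(p$values[1:4], e$values[1:4], tolerance = 1e-8)
  expect_equal(p$var_frac, (e$values / sum(e$values))[seq_along(p$var_frac)],
               tolerance = 1e-8)
  for (j in 1:4)
    expect_equal(abs(sum(as.numeric(p$movies[[j]]) * e$vectors[, j])), 1,
                 tolerance = 1e-6)
  # eigen-movies orthonormal; eigenvalue sum conserves total pixel energy
  V <- vapply(p$movies, as.numeric, numeric(ncol(X)))
  expect_equal(crossprod(V), diag(4), tolerance = 1e-8)
  expect_equal(sum(p$values), sum(X^2), tolerance = 1e-6)
  # centered variant against prcomp
  pc <- pca_templates(samples, k = 3, half_width = 2, pixel_size = 0.5,
                      blob_sd = 0.4, center = TRUE)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(pc$values[1:3] / (nrow(X)), (pr$sdev^2 * (nrow(X) - 1) / nrow(X))[1:3],
               tolerance = 1e-6)
})

test_that("PCA separates a common template from a planted shift", {
  base <- array(0, dim = c(4, 1, 2))
  base[, 1, 1] <- c(-1, -0.4, 0.4, 1)
  samples <- lapply(1:30, function(i) {
    s <- base
    s[, 1, 2] <- s[, 1, 2] + if (i %% 2 == 0) 0.5 else -0.5
    mk_sample(s)
  })
  p <- pca_templates(samples, k = 3, half_width = 2, pixel_size = 0.25)
  # two distinct images span exactly two dimensions: PC1 recovers the
  # shared (mean) pattern, PC2 the shift dipole
  expect_equal(length(p$var_frac), 2)
  expect_gt(p$var_frac[1], p$var_frac[2])
  m1 <- as.numeric(p$movies[[1]]); mm <- as.numeric(p$mean)
  expect_gt(abs(cor(m1, mm)), 0.99)
  pc2 <- p$movies[[2]]
  col_profile <- apply(pc2, 2, sum)      # collapse x and time
  expect_lt(min(col_profile) * max(col_profile), 0)  # dipole signs
  # degenerate case: identical samples -> PC1 explains everything
  same <- lapply(1:5, function(i) mk_sample(base))
  pd <- pca_templates(same, k = 2, half_width = 2, pixel_size = 0.25)
  expect_gt(pd$var_frac[1], 1 - 1e-9)
})

test_that("rail diagrams average the on-axis band and show motion as a ridge", {
  tt <- toy_trajectory(rbind(c(-3, 0), c(9, 9)), c(0, 0), n_frames = 170)
  spec <- sample_spec("io_random")
  s <- extract_sample(tt, 85, c(tt$positions[1, 85, 1], 0), spec, angle = 0)
  mov <- render_movie(list(s))
  r <- rail_diagram(mov)
  expect_equal(dim(r), c(68, 40))
  # row-mean oracle: band is the two central pixel rows
  cy <- seq(-4.875, 4.875, by = 0.25)
  rows <- which(abs(cy) <= 0.15)
  expect_equal(length(rows), 2)
  expect_equal(r[10, ], rowMeans(mov[, rows, 10]), tolerance = 1e-12)
  # ridge argmax moves at the agent speed
  amax <- apply(r, 1, which.max)
  fitv <- coef(lm(cy[amax] ~ attr(r, "times")))[2]
  expect_equal(unname(fitv), 14.5, tolerance = 0.6)
  expect_error(rail_diagram(structure(mov, pixel_size = 2, half_width = 4,
                                      class = "template_movie")), "band")
})

test_that("line fitting recovers noiseless parameters and beats a grid search", {
  xs <- seq(-4.875, 4.875, by = 0.25)
  ts <- seq(0, 0.79, length.out = 68)
  den <- sqrt(1 + 13.5^2)
  rr <- outer(ts, xs, function(t, x)
    pmax(0, 1 - abs(((2.5 - 13.5 * t - x) / den) / 0.16)^3))
  attr(rr, "times") <- ts; attr(rr, "xs") <- xs
  class(rr) <- "rail_diagram"
  f <- fit_lines(rr, 1, denominator = "geometric")
  expect_lt(abs(f$lines$p - 2.5), 0.05)
  expect_lt(abs(f$lines$v - (-13.5)), 0.2)
  expect_gt(f$correlation, 0.999)
  # the printed (1 + v^2) parametrization gives the same line, rescaled s
  fp <- fit_lines(rr, 1, denominator = "printed")
  expect_lt(abs(fp$lines$p - 2.5), 0.05)
  expect_lt(abs(fp$lines$v - (-13.5)), 0.2)
  # coarse grid-search oracle: the simplex optimum is at least as good
  grid_best <- -Inf
  rv <- as.vector((rr - min(rr)) / (max(rr) - min(rr)))
  ttm <- matrix(ts, 68, 40); xxm <- matrix(xs, 68, 40, byrow = TRUE)
  for (p0 in seq(1, 4, length.out = 13))
    for (v0 in seq(-16, -11, length.out = 11))
      for (s0 in c(0.08, 0.16, 0.32)) {
        h <- (p0 + v0 * ttm - xxm) / sqrt(1 + v0^2)
        pat <- pmax(0, 1 - abs(h / s0)^3)
        if (sd(pat) > 0) grid_best <- max(grid_best, cor(rv, as.vector(pat)))
      }
  expect_gte(f$correlation, grid_best - 1e-9)
  expect_error(fit_lines(structure(matrix(1, 10, 10),
                                   times = 1:10, xs = 1:10,
                                   class = "rail_diagram")), "flat")
})

test_that("line fitting is robust to additive noise on the rail", {
  xs <- seq(-4.875, 4.875, by = 0.25)
  ts <- seq(0, 0.79, length.out = 68)
  den <- sqrt(1 + 13.5^2)
  base <- outer(ts, xs, function(t, x)
    pmax(0, 1 - abs(((2.5 - 13.5 * t - x) / den) / 0.16)^3))
  withr::local_seed(13)
  errs <- replicate(20, {
    rr <- base + matrix(rnorm(length(base), 0, 0.05), nrow(base))
    attr(rr, "times") <- ts; attr(rr, "xs") <- xs
    class(rr) <- "rail_diagram"
    f <- fit_lines(rr, 1, denominator = "geometric")
    c(f$lines$p - 2.5, f$lines$v + 13.5)
  })
  expect_lt(abs(mean(errs[1, ])), 0.1)
  expect_lt(abs(mean(errs[2, ])), 0.3)
})
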