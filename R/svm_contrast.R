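# Classification movies: a linear support-vector machine contrasting two
# sample classes (exploration vs first catch-up saccades), its
# cross-validated accuracy against the majority-class chance level, and the
# weight vector reshaped into a spatiotemporal classification movie.

#' Majority-class chance level
#'
#' Expected accuracy of a classifier that always answers the larger class,
#' in percent.
#'
#' @param n_pos,n_neg Class sample counts.
#' @return Percentage in `[50, 100]`.
#' @export
chance_level <- function(n_pos, n_neg) {
  if (n_pos + n_neg <= 0) stop("empty sample")
  100 * max(n_pos, n_neg) / (n_pos + n_neg)
}

#' Event sample counts for the four observers of the reference experiment
#'
#' Per-observer counts of detection events (D), exploration saccades (ES),
#' first catch-up saccades (CS1) and smooth-movement episodes (SME) entering
#' the template analyses of the chase-detection eye-tracking experiment the
#' stimulus model is calibrated to. The ES and CS1 columns determine the
#' majority-class chance levels of the saccade-contrast classifier.
#'
#' @return Data frame with columns `subject`, `D`, `ES`, `CS1`, `SME`.
#' @export
observer_event_counts <- function() {
  data.frame(subject = 1:4,
             D = c(737, 769, 842, 831),
             ES = c(10760, 8272, 11859, 7606),
             CS1 = c(3580, 3566, 4271, 2467),
             SME = c(14655, 12741, 17101, 7495))
}

# stratified fold assignment
.strat_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

# linear SVM weight vector from an e1071 model
.svm_weights <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

#' Train a linear SVM contrast between two sample classes
#'
#' Renders both sample sets, trains a linear support-vector machine on the
#' vectorized movies with the cost parameter chosen by nested
#' cross-validation, reports stratified k-fold cross-validation accuracy
#' against the majority-class chance level, and reshapes the weight vector
#' into a classification movie. Binary maxima/minima movies threshold the
#' weights at mean +/- 2 sd.
#'
#' @param samples_pos,samples_neg Lists of `aligned_sample` objects (equal
#'   length within and across classes).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed (fold assignment).
#' @param costs Candidate SVM cost values for nested selection.
#' @param half_width,pixel_size,blob_sd,shape,ring_radius,ring_sd
#'   Rasterization (see [render_movie()]).
#' @return A `contrast_result` list: `cv_accuracy` (%), `chance_accuracy`
#'   (%), `cost`, `weight_movie`, `movie_pos`, `movie_neg` (binary
#'   threshold movies), `n_pos`, `n_neg`.
#' @export
train_contrast <- function(samples_pos, samples_neg, folds = 5, seed = 1L,
                           costs = c(0.01, 0.1, 1), half_width = 5,
                           pixel_size = 0.25, blob_sd = 0.5,
                           shape = c("gaussian", "ring"), ring_radius = 0.5,
                           ring_sd = 0.125) {
  shape <- match.arg(shape)
  sd_r <- if (shape == "gaussian") blob_sd else ring_sd
  n_pos <- length(samples_pos); n_neg <- length(samples_neg)
  if (n_pos < folds || n_neg < folds)
    stop("need at least `folds` samples per class")
  render1 <- function(s) {
    nt <- dim(s$coords)[1]
    npix <- round(2 * half_width / pixel_size)
    m <- array(0, dim = c(npix, npix, nt))
    for (t in seq_len(nt))
      m[, , t] <- .deposit_frame(m[, , t], s$coords[t, , , drop = TRUE],
                                 half_width, pixel_size, sd_r, shape,
                                 ring_radius)
    as.vector(m)
  }
  X <- t(vapply(c(samples_pos, samples_neg), render1,
                numeric(length(render1(samples_pos[[1]])))))
  y <- factor(rep(c("pos", "neg"), c(n_pos, n_neg)), levels = c("neg", "pos"))
  dims <- c(round(2 * half_width / pixel_size), round(2 * half_width / pixel_size),
            dim(samples_pos[[1]]$coords)[1])
  with_seed(as.integer(seed %% 2147480000), {
    fold <- .strat_folds(y, folds)
    # nested cost selection on the first training split
    pick_cost <- function(tr_idx) {
      if (length(costs) == 1) return(costs)
      inner <- .strat_folds(y[tr_idx], min(3, folds))
      acc <- vapply(costs, function(C) {
        mean(vapply(seq_len(max(inner)), function(j) {
          it <- tr_idx[inner != j]; iv <- tr_idx[inner == j]
          m <- e1071::svm(X[it, , drop = FALSE], y[it], kernel = "linear",
                          cost = C, scale = FALSE)
          mean(stats::predict(m, X[iv, , drop = FALSE]) == y[iv])
        }, numeric(1)))
      }, numeric(1))
      costs[which.max(acc)]
    }
    C <- pick_cost(which(fold != 1))
    correct <- logical(length(y))
    for (j in seq_len(folds)) {
      tr_i <- which(fold != j); te_i <- which(fold == j)
      m <- e1071::svm(X[tr_i, , drop = FALSE], y[tr_i], kernel = "linear",
                      cost = C, scale = FALSE)
      correct[te_i] <- stats::predict(m, X[te_i, , drop = FALSE]) == y[te_i]
    }
    final <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE)
    w <- .svm_weights(final)
    thr <- mean(w) + 2 * stats::sd(w)
    weight_movie <- array(w, dim = dims)
    structure(list(cv_accuracy = 100 * mean(correct),
                   chance_accuracy = chance_level(n_pos, n_neg),
                   cost = C,
                   weight_movie = structure(weight_movie,
                                            pixel_size = pixel_size,
                                            half_width = half_width,
                                            class = "template_movie"),
                   movie_pos = weight_movie > thr,
                   movie_neg = weight_movie < mean(w) - 2 * stats::sd(w),
                   n_pos = n_pos, n_neg = n_neg),
              class = "contrast_result")
  })
}
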