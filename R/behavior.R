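# Detection-behavior summaries: log-normal detection-time fits, Bernoulli
# detection rates (both with percentile-bootstrap intervals), and the
# rolling ten-trial accuracy feedback shown to subjects.

#' Log-normal fit to detection times
#'
#' Maximum-likelihood fit of `log(y) ~ N(mu, sigma)`; the mean detection
#' time is `exp(mu + sigma^2 / 2)`, with a percentile bootstrap confidence
#' interval.
#'
#' @param times Positive detection times in seconds (omissions excluded).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `mu`, `sigma`, `mean_time`, `ci` and `n`.
#' @export
fit_lognormal <- function(times, n_boot = 1000, seed = 1L, conf = 0.95) {
  if (any(!is.finite(times)) || any(times <= 0))
    stop("detection times must be positive and finite")
  n <- length(times)
  if (n < 2) stop("need at least two detection times")
  lt <- log(times)
  mu <- mean(lt)
  sigma <- sqrt(mean((lt - mu)^2))       # MLE (1/n) variance
  mean_time <- exp(mu + sigma^2 / 2)
  ci <- with_seed(as.integer(seed %% 2147480000), {
    reps <- vapply(seq_len(n_boot), function(b) {
      s <- lt[sample.int(n, n, replace = TRUE)]
      m <- mean(s); sg2 <- mean((s - m)^2)
      exp(m + sg2 / 2)
    }, numeric(1))
    stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  list(mu = mu, sigma = sigma, mean_time = mean_time, ci = ci, n = n)
}

#' Bernoulli detection rate
#'
#' Maximum-likelihood detection rate with a percentile-bootstrap interval.
#'
#' @param successes Logical (or 0/1) vector of per-trial outcomes.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `rate`, `ci` and `n`.
#' @export
fit_bernoulli <- function(successes, n_boot = 1000, seed = 1L, conf = 0.95) {
  x <- as.logical(successes)
  if (length(x) < 1 || anyNA(x)) stop("invalid success vector")
  n <- length(x)
  rate <- mean(x)
  ci <- with_seed(as.integer(seed %% 2147480000), {
    reps <- vapply(seq_len(n_boot), function(b)
      mean(x[sample.int(n, n, replace = TRUE)]), numeric(1))
    stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  list(rate = rate, ci = ci, n = n)
}

#' Accuracy over consecutive ten-trial blocks
#'
#' The proportion of correct trials in each consecutive block of `window`
#' trials, i.e. the feedback subjects saw after every ten trials.
#'
#' @param successes Logical (or 0/1) vector in trial order.
#' @param window Block size.
#' @return Numeric vector, one value per complete block.
#' @export
rolling_accuracy <- function(successes, window = 10) {
  x <- as.numeric(successes)
  n_blocks <- length(x) %/% window
  if (n_blocks == 0) return(numeric(0))
  vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * window + 1):(b * window)]), numeric(1))
}

#' Summarize a trial table of detection behavior
#'
#' Fits detection-time and detection-rate models separately per condition.
#' Omitted trials (no response inside the trial duration) count as
#' incorrect and are excluded from the time fits.
#'
#' @param trials Data frame with columns `condition` (`"DC"`/`"NC"`),
#'   `time_s` (NA for omissions) and `correct` (logical).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Nested list by condition with `time_fit`, `rate_fit`, and the
#'   overall `rolling` accuracy.
#' @export
summarize_behavior <- function(trials, n_boot = 1000, seed = 1L) {
  out <- list()
  for (cond in unique(trials$condition)) {
    tt <- trials[trials$condition == cond, ]
    correct <- tt$correct & !is.na(tt$time_s)
    times <- tt$time_s[correct]
    out[[cond]] <- list(
      time_fit = if (length(times) >= 2)
        fit_lognormal(times, n_boot, seed) else NULL,
      rate_fit = fit_bernoulli(tt$correct & !is.na(tt$time_s), n_boot, seed))
  }
  out$rolling <- rolling_accuracy(trials$correct & !is.na(trials$time_s))
  out
}
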