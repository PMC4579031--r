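# Small shared helpers.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random stream seeded to `seed`, then restores
#' the previous stream, so callers' randomness is unaffected.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# run-length segments of a logical vector: data.frame(start, end) of TRUE runs
.runs_true <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# absolute angular difference in degrees, in [0, 180]
.ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# circular mean of angles in degrees, weighted
.circ_mean <- function(a, w = rep(1, length(a))) {
  s <- sum(w * .sind(a)); c <- sum(w * .cosd(a))
  (atan2(s, c) * 180 / pi) %% 360
}
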