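# Complex events: pursuit and exploration, built from the basic tier, plus
# saccade labeling (exploration saccades vs ordered catch-up saccades) and
# frame-wise agreement metrics between two labeled streams.

.parse_agents <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0)
  else as.integer(strsplit(s, ",")[[1]])
}

#' Aggregate basic events into pursuit and exploration
#'
#' Pursuit starts with a fast smooth movement, or with two consecutive slow
#' smooth movements separated by a single saccade that focus overlapping
#' agent sets (in which case the first SSM is reassigned retroactively and
#' the intervening saccade becomes the pursuit's first catch-up saccade).
#' Pursuit continues while the focused agent sets of consecutive
#' fixation/SSM/FSM events overlap (nonempty intersection), with at most
#' one saccade between them; every pursuit must contain at least one FSM,
#' otherwise it is demoted to exploration. All remaining fixations and SSMs
#' form exploration. Saccades are assigned to the complex event of the
#' basic event that follows them; uncoded stretches break complex events.
#'
#' @param basics A `basic_events` data frame (time-ordered).
#' @param max_join_gap_frames Maximal number of uncoded frames across which
#'   two basic events are still treated as consecutive.
#' @return A `complex_events` data frame: `kind`, `f_start`, `f_end`,
#'   `t_start`, `t_end`, `agents`, `members` (comma-separated row indices
#'   into `basics`).
#' @export
extract_complex <- function(basics, max_join_gap_frames = 3) {
  n <- nrow(basics)
  if (n == 0)
    return(structure(data.frame(kind = character(0), f_start = integer(0),
                                f_end = integer(0), t_start = numeric(0),
                                t_end = numeric(0), agents = character(0),
                                members = character(0)),
                     class = c("complex_events", "data.frame")))
  is_sac <- basics$kind == "saccade"
  segs <- list()   # each: list(kind, rows, agents)
  cur <- NULL      # current segment under construction
  close_seg <- function() {
    if (!is.null(cur)) segs[[length(segs) + 1L]] <<- cur
    cur <<- NULL
  }
  # connection between consecutive basic rows i (earlier) and j (later):
  # "direct" (adjacent), "saccade" (exactly one saccade between, all
  # adjacent), or "broken"
  connection <- function(i, j) {
    between <- which(!seq_len(n) %in% c(i, j) & seq_len(n) > i & seq_len(n) < j)
    gap_ok <- function(a, b) basics$f_start[b] - basics$f_end[a] - 1 <=
      max_join_gap_frames
    if (length(between) == 0)
      return(if (gap_ok(i, j)) "direct" else "broken")
    if (length(between) == 1 && is_sac[between] &&
        gap_ok(i, between) && gap_ok(between, j)) return("saccade")
    "broken"
  }
  prev_row <- NULL
  for (r in seq_len(n)) {
    if (is_sac[r]) next
    S <- .parse_agents(basics$agents[r])
    conn <- if (is.null(prev_row)) "broken" else connection(prev_row, r)
    prev_S <- if (is.null(prev_row)) integer(0)
      else .parse_agents(basics$agents[prev_row])
    if (!is.null(cur) && cur$kind == "pursuit") {
      if (conn != "broken" && length(intersect(S, prev_S)) > 0) {
        cur$rows <- c(cur$rows, r)
        cur$agents <- union(cur$agents, S)
      } else {
        close_seg()
      }
    }
    if (is.null(cur) || cur$kind != "pursuit") {
      started <- FALSE
      if (basics$kind[r] == "FSM") {
        close_seg()
        cur <- list(kind = "pursuit", rows = r, agents = S)
        started <- TRUE
      } else if (basics$kind[r] == "SSM" && !is.null(prev_row) &&
                 basics$kind[prev_row] == "SSM" && conn == "saccade" &&
                 length(intersect(S, prev_S)) > 0) {
        # retroactive start at the previous SSM
        if (!is.null(cur)) {
          cur$rows <- setdiff(cur$rows, prev_row)
          if (length(cur$rows) == 0) cur <- NULL
        }
        close_seg()
        cur <- list(kind = "pursuit", rows = c(prev_row, r),
                    agents = union(prev_S, S))
        started <- TRUE
      }
      if (!started) {
        if (!is.null(cur) && cur$kind == "exploration" && conn != "broken") {
          cur$rows <- c(cur$rows, r)
          cur$agents <- union(cur$agents, S)
        } else {
          close_seg()
          cur <- list(kind = "exploration", rows = r, agents = S)
        }
      }
    }
    prev_row <- r
  }
  close_seg()
  # demote pursuits without FSM
  for (i in seq_along(segs))
    if (segs[[i]]$kind == "pursuit" &&
        !any(basics$kind[segs[[i]]$rows] == "FSM"))
      segs[[i]]$kind <- "exploration"
  # assign each saccade to the segment of the following basic event
  seg_of_row <- integer(n)
  for (i in seq_along(segs)) seg_of_row[segs[[i]]$rows] <- i
  for (r in which(is_sac)) {
    nxt <- r + 1L
    while (nxt <= n && is_sac[nxt]) nxt <- nxt + 1L
    if (nxt <= n && seg_of_row[nxt] > 0 &&
        basics$f_start[nxt] - basics$f_end[r] - 1 <= max_join_gap_frames &&
        basics$f_start[r] >
          if (r > 1) basics$f_end[r - 1] - 1 else -1) {
      i <- seg_of_row[nxt]
      segs[[i]]$rows <- sort(c(segs[[i]]$rows, r))
      seg_of_row[r] <- i
    }
  }
  out <- do.call(rbind, lapply(segs, function(sg) {
    rows <- sort(sg$rows)
    data.frame(kind = sg$kind,
               f_start = min(basics$f_start[rows]),
               f_end = max(basics$f_end[rows]),
               t_start = min(basics$t_start[rows]),
               t_end = max(basics$t_end[rows]),
               agents = paste(sort(unique(sg$agents)), collapse = ","),
               members = paste(rows, collapse = ","))
  }))
  out <- out[order(out$f_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("complex_events", "data.frame"))
}

#' Label saccades as exploration or ordered catch-up saccades
#'
#' A saccade immediately followed by a pursuit-member basic event is a
#' catch-up saccade (CS), ordered within its pursuit (CS1, CS2, ...); a
#' saccade immediately followed by exploration is an exploration saccade
#' (ES); a trailing saccade with no following coded event stays unlabeled.
#'
#' @param basics A `basic_events` data frame.
#' @param complexes The matching `complex_events` data frame.
#' @return Data frame `row` (index into `basics`), `label` (`"ES"`,
#'   `"CS"`, or `NA`), `cs_order` (integer or `NA`).
#' @export
label_saccades <- function(basics, complexes) {
  n <- nrow(basics)
  is_sac <- basics$kind == "saccade"
  seg_of_row <- integer(n)
  for (i in seq_len(nrow(complexes)))
    seg_of_row[as.integer(strsplit(complexes$members[i], ",")[[1]])] <- i
  out <- data.frame(row = which(is_sac), label = NA_character_,
                    cs_order = NA_integer_)
  counters <- integer(nrow(complexes))
  for (k in seq_len(nrow(out))) {
    r <- out$row[k]
    i <- seg_of_row[r]
    if (i == 0) next
    if (complexes$kind[i] == "pursuit") {
      counters[i] <- counters[i] + 1L
      out$label[k] <- "CS"
      out$cs_order[k] <- counters[i]
    } else {
      out$label[k] <- "ES"
    }
  }
  out
}

#' Frame-wise agreement between two labeled streams
#'
#' Accumulates a 2 x 2 confusion table over the frames where either stream
#' asserts one of the two classes (frames where a stream asserts neither
#' count against the positive class) and reports accuracy, sensitivity,
#' specificity and the Matthews correlation coefficient, with stream `a` as
#' the reference.
#'
#' @param a,b Character vectors of per-frame labels on the same time base.
#' @param positive,negative The two class labels.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `mcc` and
#'   the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
compare_streams <- function(a, b, positive, negative) {
  stopifnot(length(a) == length(b))
  use <- a %in% c(positive, negative) | b %in% c(positive, negative)
  if (!any(use)) stop("no frames assert either class")
  ap <- a[use] == positive
  bp <- b[use] == positive
  tp <- sum(ap & bp); fn <- sum(ap & !bp)
  fp <- sum(!ap & bp); tn <- sum(!ap & !bp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = mcc, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Frame-wise event recovery score against truth labels
#'
#' Converts truth labels and recovered events to per-frame labels (saccade
#' subtypes collapsed) and computes the multi-class Matthews correlation
#' over codeable frames. Frames within `boundary_tol` frames of a truth
#' event boundary are excluded by default: the 20 ms measurement smoothing
#' makes event boundaries ill-defined to roughly the filter width, so
#' boundary frames measure filter delay, not classification quality.
#' Missing frames and frames the truth leaves uncoded are always excluded.
#'
#' @param truth Truth event data frame (`kind`, `t_start`, `t_end`).
#' @param events Recovered `basic_events`.
#' @param n_frames Number of display frames.
#' @param missing Logical vector of missing frames (optional).
#' @param boundary_tol Frames to drop around each truth boundary.
#' @param frame_rate Frame rate (Hz).
#' @return Multi-class Matthews correlation coefficient.
#' @export
recovery_mcc <- function(truth, events, n_frames, missing = NULL,
                         boundary_tol = 2, frame_rate = 85) {
  tru <- truth_to_frames(truth, n_frames, frame_rate)
  rec <- events_to_frames(events, n_frames)
  keep <- tru != "none"
  if (!is.null(missing)) keep <- keep & !missing
  if (boundary_tol > 0) {
    bounds <- unique(c(floor(truth$t_start * frame_rate) + 1L,
                       floor(truth$t_end * frame_rate) + 1L))
    for (d in -boundary_tol:boundary_tol) {
      bb <- bounds + d
      bb <- bb[bb >= 1 & bb <= n_frames]
      keep[bb] <- FALSE
    }
  }
  mcc_multiclass(tru[keep], rec[keep])
}

#' Multi-class Matthews correlation between two label vectors
#'
#' The multi-category generalization of the Matthews correlation
#' coefficient, computed from the full confusion matrix over the selected
#' frames.
#'
#' @param a,b Character vectors of per-frame labels.
#' @param exclude Labels marking frames to drop when present in `a`
#'   (e.g. uncodeable stretches of the reference).
#' @return Scalar in `[-1, 1]`.
#' @export
mcc_multiclass <- function(a, b, exclude = character(0)) {
  keep <- !(a %in% exclude)
  a <- a[keep]; b <- b[keep]
  lev <- sort(unique(c(a, b)))
  C <- table(factor(a, lev), factor(b, lev))
  s <- sum(C)
  corr <- s * sum(diag(C)) - sum(rowSums(C) * colSums(C))
  d1 <- s^2 - sum(rowSums(C)^2)
  d2 <- s^2 - sum(colSums(C)^2)
  if (d1 == 0 || d2 == 0) return(NA_real_)
  corr / sqrt(d1) / sqrt(d2)
}
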