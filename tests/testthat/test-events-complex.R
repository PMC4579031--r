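# worked examples of the pursuit/exploration aggregation rules on
# hand-built event streams

test_that("fixation-saccade-fixation is one exploration with an ES", {
  b <- rbind(mk_event("fixation", 1, 30, "1"),
             mk_event("saccade", 31, 34),
             mk_event("fixation", 35, 70, "2"))
  cx <- extract_complex(b)
  expect_equal(cx$kind, "exploration")
  expect_equal(nrow(cx), 1)
  lab <- label_saccades(b, cx)
  expect_equal(lab$label, "ES")
})

test_that("chained agent-set overlap joins smooth events into one pursuit", {
  b <- rbind(mk_event("saccade", 1, 3),
             mk_event("FSM", 4, 30, "3"),
             mk_event("saccade", 31, 33),
             mk_event("SSM", 34, 60, "3,4"),
             mk_event("saccade", 61, 63),
             mk_event("FSM", 64, 90, "4"))
  cx <- extract_complex(b)
  expect_equal(cx$kind, "pursuit")
  expect_equal(nrow(cx), 1)
  expect_equal(cx$f_start, 1)
  expect_equal(cx$f_end, 90)
  lab <- label_saccades(b, cx)
  expect_equal(lab$label, rep("CS", 3))
  expect_equal(lab$cs_order, 1:3)
})

test_that("disjoint slow smooth movements without FSM stay exploration", {
  b <- rbind(mk_event("SSM", 1, 30, "1"),
             mk_event("saccade", 31, 33),
             mk_event("SSM", 34, 60, "2"))
  cx <- extract_complex(b)
  expect_true(all(cx$kind == "exploration"))
})

test_that("two overlapping SSMs start a pursuit retroactively when FSM follows", {
  b <- rbind(mk_event("fixation", 1, 20, "5"),
             mk_event("saccade", 21, 23),
             mk_event("SSM", 24, 50, "1,2"),
             mk_event("saccade", 51, 53),
             mk_event("SSM", 54, 80, "1"),
             mk_event("saccade", 81, 83),
             mk_event("FSM", 84, 110, "1"))
  cx <- extract_complex(b)
  expect_equal(cx$kind, c("exploration", "pursuit"))
  # pursuit starts retroactively at the first SSM (frame 24); the saccade
  # preceding it is followed by a pursuit member, so it attaches as CS1
  expect_equal(cx$f_start[2], 21)
  lab <- label_saccades(b, cx)
  expect_equal(lab$label, c("CS", "CS", "CS"))
  expect_equal(lab$cs_order, 1:3)
})

test_that("CS orders reset across pursuits and trailing saccades stay unlabeled", {
  b <- rbind(mk_event("saccade", 1, 3), mk_event("FSM", 4, 30, "1"),
             mk_event("fixation", 31, 60, "9"),
             mk_event("saccade", 61, 63), mk_event("FSM", 64, 90, "2"),
             mk_event("saccade", 91, 93))
  cx <- extract_complex(b)
  expect_equal(sum(cx$kind == "pursuit"), 2)
  lab <- label_saccades(b, cx)
  expect_equal(lab$cs_order[1:2], c(1L, 1L))
  expect_true(is.na(lab$label[3]))
})

test_that("removing all FSMs removes all pursuits", {
  obs <- fix_observer()
  ev <- obs$events[obs$events$kind != "FSM", ]
  cx <- extract_complex(ev)
  expect_equal(sum(cx$kind == "pursuit"), 0)
})

test_that("complex events partition the coded stream without overlap", {
  obs <- fix_observer()
  cx <- extract_complex(obs$events)
  lab <- events_to_frames(cx, nrow(obs$fused))
  ord <- order(cx$f_start)
  expect_true(all(cx$f_start[ord][-1] > cx$f_end[ord][-nrow(cx)]))
  expect_true(all(cx$kind %in% c("pursuit", "exploration")))
  # every pursuit contains at least one FSM member
  for (i in which(cx$kind == "pursuit")) {
    rows <- as.integer(strsplit(cx$members[i], ",")[[1]])
    expect_true(any(obs$events$kind[rows] == "FSM"))
  }
})

test_that("stream agreement metrics match the textbook formulas", {
  a <- rep(c("CS", "ES"), c(40, 60))
  expect_equal(compare_streams(a, a, "CS", "ES")$accuracy, 1)
  expect_equal(compare_streams(a, a, "CS", "ES")$mcc, 1)
  b <- rep(c("ES", "CS"), c(40, 60))
  expect_equal(compare_streams(a, b, "CS", "ES")$mcc, -1)
  withr::local_seed(9)
  for (i in 1:20) {
    n <- 200
    a <- sample(c("CS", "ES"), n, replace = TRUE)
    b <- sample(c("CS", "ES"), n, replace = TRUE, prob = c(0.3, 0.7))
    m <- compare_streams(a, b, "CS", "ES")
    tp <- sum(a == "CS" & b == "CS"); fn <- sum(a == "CS" & b == "ES")
    fp <- sum(a == "ES" & b == "CS"); tn <- sum(a == "ES" & b == "ES")
    expect_equal(m$accuracy, (tp + tn) / n)
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$mcc, (tp * tn - fp * fn) /
                   sqrt(tp + fp) / sqrt(tp + fn) / sqrt(tn + fp) / sqrt(tn + fn))
    # class swap: accuracy and MCC unchanged, sensitivity/specificity swap
    ms <- compare_streams(a, b, "ES", "CS")
    expect_equal(ms$accuracy, m$accuracy)
    expect_equal(ms$mcc, m$mcc)
    expect_equal(ms$sensitivity, m$specificity)
    expect_equal(ms$specificity, m$sensitivity)
  }
})
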