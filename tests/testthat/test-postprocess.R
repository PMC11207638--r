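test_that("weighting functions evaluate to their printed closed forms", {
  expect_equal(weight_value("W1", 5, 0), 3)
  expect_equal(weight_value("W2", 99, 0), 0.5)
  expect_equal(weight_value("W1", 5, 0:2), c(3, 2, 1))
  expect_equal(weight_value("W3", 5, 0:2), c(9, 4, 1))
  expect_equal(weight_value("W4", 5, 0:2), log(c(4, 3, 2)))
  expect_equal(weight_value("W5", 7, 0:2), 1 / log(c(2, 3, 4)))
  # clamping: no negative evidence at extreme offsets of even windows
  expect_true(all(weight_value("W1", 4, 0:4) >= 0))
  expect_true(all(weight_value("W4", 4, 0:4) >= 0))
  expect_error(weight_value("W9", 5, 0), "unknown")
})

test_that("correct_window reproduces hand-evaluated votes and tie rules", {
  expect_identical(correct_window(c("A", "A", "B", "A", "A"), "W1"), "A")
  # even window: midpoint 3, weights 1,2,3,2 -> B wins 5 to 3
  expect_identical(correct_window(c("A", "A", "B", "B"), "W1"), "B")
  for (fn in paste0("W", 1:5)) {
    expect_identical(correct_window("Q", fn), "Q")
  }
  # score tie -> higher raw count wins
  expect_identical(correct_window(c("B", "A", "A"), "W5"), "A")
})

test_that("correct_window agrees with a brute-force scorer on all short streams", {
  labs <- c("A", "B", "NULL")
  for (fn in c("W1", "W4")) {
    got <- character(0); want <- character(0)
    for (n in 1:5) {
      for (w in enumerate_streams(n, labs)) {
        got[length(got) + 1L] <- correct_window(w, fn)
        want[length(want) + 1L] <- brute_correct_window(w, fn)
      }
    }
    expect_identical(got, want, label = fn)
  }
})

test_that("centered correction overrules isolated blips and conserves length", {
  p <- prediction_stream(c("A","A","A","A","B","A","A","A","A"))
  out <- correct_stream(p, "W1", ws_count = 3)
  expect_identical(out$labels, rep("A", 9))
  expect_equal(length(out), length(p))
  # constant streams are fixed points for every fn and ws
  const <- prediction_stream(rep("A", 100))
  for (fn in paste0("W", 1:5)) {
    expect_identical(correct_stream(const, fn, ws_count = 11)$labels,
                     const$labels)
  }
})

test_that("ws = 1 is the identity in both modes and oversized ws passes through", {
  set.seed(14)
  p <- prediction_stream(random_label_stream(50))
  for (mode in c("centered", "literal_streaming")) {
    expect_identical(correct_stream(p, "W3", ws_count = 1,
                                    mode = mode)$labels, p$labels)
  }
  expect_warning(out <- correct_stream(p, "W1", ws_count = 51),
                 "longer than the stream")
  expect_identical(out$labels, p$labels)
})

test_that("centered mode agrees with direct window-by-window correction", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(10:40, 1)
    ws <- sample(2:7, 1)
    fn <- sample(paste0("W", 1:5), 1)
    p <- random_label_stream(n)
    out <- correct_stream(prediction_stream(p), fn, ws_count = ws)$labels
    midpoint <- ws %/% 2 + 1
    left <- midpoint - 1; right <- ws - midpoint
    for (t in seq_len(n)) {
      expected <- if (t <= left || t > n - right) p[t] else
        correct_window(p[(t - left):(t + right)], fn)
      expect_identical(out[t], expected)
    }
  }
})

test_that("literal streaming mode passes through a warm-up then lags by design", {
  p <- c(rep("A", 6), rep("B", 6))
  out <- correct_stream(prediction_stream(p), "W1", ws_count = 4,
                        mode = "literal_streaming")$labels
  expect_identical(out[1:4], p[1:4])      # warm-up pass-through
  # position i>ws corrects the trailing window P[i-ws .. i-1]
  expect_identical(out[5], correct_window(p[1:4], "W1"))
  expect_identical(out[12], correct_window(p[8:11], "W1"))
  expect_equal(length(out), length(p))
})

test_that("W4/W5 corrections are invariant to the log base", {
  set.seed(16)
  for (rep in 1:20) {
    p <- prediction_stream(random_label_stream(60))
    ws <- sample(c(3, 5, 8, 13), 1)
    for (fn in c("W4", "W5")) {
      expect_identical(
        correct_stream(p, fn, ws_count = ws)$labels,
        correct_stream(p, fn, ws_count = ws, log_base = 10)$labels)
    }
  }
})

test_that("repeated centered correction rarely changes more labels than the first pass", {
  set.seed(17)
  ok <- 0
  for (rep in 1:40) {
    p <- prediction_stream(random_label_stream(80))
    c1 <- correct_stream(p, "W1", ws_count = 7)
    c2 <- correct_stream(c1, "W1", ws_count = 7)
    if (sum(c2$labels != c1$labels) <= sum(c1$labels != p$labels)) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.95)
})

test_that("centered correction cleans corrupted streams: precision up, insertions down", {
  lab <- rep("NULL", 8000)
  for (s in c(500, 2000, 3500, 5200, 6800)) lab[s:(s + 399)] <- "Walking"
  gt <- prediction_stream(lab)
  # insertion-dominated corruption: fragmenting returns already count as
  # positives in event precision, so only a stream whose errors are mostly
  # spurious events has room for correction to raise precision
  bad <- corrupt_predictions(gt, miss_rate = 0.02, insert_rate = 0.1,
                             insert_mean_len = 6, frag_rate = 0.2,
                             frag_hole_len = 20, seed = 8)
  raw <- score_streams(gt, bad)
  fixed <- score_streams(gt, correct_stream(bad, "W4", ws_count = 640))
  expect_gt(fixed$pooled[["P"]], raw$pooled[["P"]])
  expect_gte(fixed$pooled[["F1"]], raw$pooled[["F1"]])
  expect_lt(fixed$counts[["Ip"]], raw$counts[["Ip"]])
})
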