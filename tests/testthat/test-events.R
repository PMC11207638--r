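test_that("frames_to_events reads maximal runs as half-open segments", {
  ev <- frames_to_events(c("0", "1", "1", "0", "1"), "1")
  expect_equal(ev$start, c(1, 4))
  expect_equal(ev$end, c(3, 5))
  all_cls <- frames_to_events(rep("A", 7), "A")
  expect_equal(unlist(all_cls), c(start = 0, end = 7))
  expect_equal(nrow(frames_to_events(rep("A", 7), "B")), 0)
  expect_equal(nrow(frames_to_events(character(0), "A")), 0)
})

test_that("event categorization matches hand-derived cases", {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  exact <- categorize_events(seg(0, 3), seg(0, 3))
  expect_equal(exact[["C"]], 1)
  expect_equal(sum(exact), 1)

  frag <- categorize_events(seg(2, 8), seg(3, 5, 6, 7))
  expect_equal(frag[["F"]], 1)
  expect_equal(frag[["Fp"]], 2)
  expect_equal(frag[["Ip"]], 0)
  expect_equal(frag[["D"]], 0)

  ins <- categorize_events(seg(5, 8), seg(1, 2, 5, 8))
  expect_equal(ins[["C"]], 1)
  expect_equal(ins[["Ip"]], 1)
  expect_equal(ins[["D"]], 0)

  merge_ <- categorize_events(seg(0, 2, 4, 6), seg(0, 6))
  expect_equal(merge_[["M"]], 2)
  expect_equal(merge_[["Mp"]], 1)

  expect_error(categorize_events(seg(0, 3, 2, 5), seg(0, 1)), "overlapping")
})

test_that("category counts conserve event totals and match the brute oracle exhaustively", {
  for (n in 1:6) {
    streams <- enumerate_streams(n, c("A", "NULL"))
    segs <- lapply(streams, frames_to_events, cls = "A")
    got <- list(); want <- list(); conserved <- logical(0)
    for (gt in segs) {
      for (pred in segs) {
        ct <- categorize_events(gt, pred)
        got[[length(got) + 1L]] <- ct
        want[[length(want) + 1L]] <- brute_categorize(gt, pred)
        conserved[length(conserved) + 1L] <-
          sum(ct[c("C", "D", "F", "M", "FM")]) == nrow(gt) &&
          sum(ct[c("C", "Ip", "Fp", "Mp", "FMp")]) == nrow(pred)
      }
    }
    expect_identical(got, want, label = paste("length", n))
    expect_true(all(conserved), label = paste("conservation, length", n))
  }
})

test_that("event precision/recall/F1 follow the category formulas", {
  z <- c(C = 0L, D = 0L, F = 0L, M = 0L, FM = 0L,
         Ip = 0L, Fp = 0L, Mp = 0L, FMp = 0L)
  m <- z; m["C"] <- 2L; m["Ip"] <- 1L; m["D"] <- 1L
  expect_equal(event_prf(m), c(P = 2/3, R = 2/3, F1 = 2/3))
  perfect <- z; perfect["C"] <- 5L
  expect_equal(event_prf(perfect), c(P = 1, R = 1, F1 = 1))
  # fragmentation counts as detected on both sides
  fr <- z; fr["F"] <- 1L; fr["Fp"] <- 2L
  expect_equal(event_prf(fr)[["P"]], 1)
  expect_equal(event_prf(fr)[["R"]], 1)
  # zero-event conventions
  expect_equal(event_prf(z), c(P = 1, R = 1, F1 = 1))
  del <- z; del["D"] <- 3L
  expect_equal(event_prf(del), c(P = 0, R = 0, F1 = 0))
  neg <- z; neg["C"] <- -1L
  expect_error(event_prf(neg), "negative")
})

test_that("algebraic identities hold on random streams", {
  set.seed(19)
  ok <- TRUE
  for (rep in 1:100) {
    g <- random_label_stream(60)
    p <- random_label_stream(60)
    for (cl in c("A", "B")) {
      gt <- frames_to_events(g, cl)
      pred <- frames_to_events(p, cl)
      ct <- categorize_events(gt, pred)
      met <- event_prf(ct)
      if (nrow(pred) > 0) {
        ok <- ok && isTRUE(all.equal(met[["P"]], 1 - ct[["Ip"]] / nrow(pred)))
      }
      if (nrow(gt) > 0) {
        ok <- ok && isTRUE(all.equal(met[["R"]], 1 - ct[["D"]] / nrow(gt)))
      }
    }
  }
  expect_true(ok)
})

test_that("scoring is symmetric under time reversal of both streams", {
  set.seed(23)
  for (rep in 1:20) {
    g <- random_label_stream(50)
    p <- random_label_stream(50)
    a <- score_streams(g, p, classes = c("A", "B"))
    b <- score_streams(rev(g), rev(p), classes = c("A", "B"))
    expect_equal(a$counts, b$counts)
    expect_equal(a$pooled, b$pooled)
  }
})

test_that("stream scoring pools categories and matches a per-class brute scorer", {
  set.seed(29)
  g <- random_label_stream(120, c("A", "B", "C", "NULL"),
                           c(0.1, 0.1, 0.05, 0.75))
  p <- random_label_stream(120, c("A", "B", "C", "NULL"),
                           c(0.1, 0.1, 0.05, 0.75))
  sc <- score_streams(g, p, classes = c("A", "B", "C"))
  brute_total <- c(C = 0L, D = 0L, F = 0L, M = 0L, FM = 0L,
                   Ip = 0L, Fp = 0L, Mp = 0L, FMp = 0L)
  for (cl in c("A", "B", "C")) {
    bc <- brute_categorize(frames_to_events(g, cl), frames_to_events(p, cl))
    expect_equal(unlist(sc$per_class[sc$per_class$class == cl,
                                     names(bc)]) , bc,
                 ignore_attr = TRUE)
    brute_total <- brute_total + bc
  }
  expect_equal(sc$counts, brute_total)
  expect_equal(sc$pooled, event_prf(brute_total))

  # perfect prediction
  perf <- score_streams(g, g, classes = c("A", "B", "C"))
  expect_equal(unname(perf$pooled), c(1, 1, 1))
  expect_equal(unname(perf$window), c(1, 1, 1))

  # total deletion: all-NULL prediction
  dele <- score_streams(g, rep("NULL", 120), classes = c("A", "B", "C"))
  expect_equal(dele$pooled[["R"]], 0)
  expect_equal(sum(dele$counts[c("Ip", "Fp", "Mp", "FMp")]), 0)
})
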