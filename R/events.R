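#' Maximal runs of one class as half-open event segments
#'
#' An event is a maximal run of frames carrying the same class label, with a
#' start and a stop; segments are reported half-open `[start, end)` in frame
#' (stride) units, 0-based.
#'
#' @param labels character vector of per-frame labels, or a
#'   [prediction_stream()].
#' @param cls the class of interest.
#' @return data.frame with columns `start`, `end` (sorted, disjoint).
#' @export
frames_to_events <- function(labels, cls) {
  if (inherits(labels, "prediction_stream")) labels <- labels$labels
  if (!length(labels)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(labels == cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# overlap = sharing at least one frame; optionally require the shared span to
# be at least min_overlap_frac of the shorter segment.
segments_overlap <- function(a_start, a_end, b_start, b_end,
                             min_overlap_frac = 0) {
  shared <- pmin(a_end, b_end) - pmax(a_start, b_start)
  if (min_overlap_frac <= 0) return(shared > 0)
  shared >= min_overlap_frac * pmin(a_end - a_start, b_end - b_start)
}

check_segments <- function(seg, what) {
  if (!nrow(seg)) return(invisible(seg))
  if (any(seg$end <= seg$start)) stop(what, ": empty or inverted segment")
  if (is.unsorted(seg$start)) stop(what, ": segments not sorted")
  if (nrow(seg) > 1L && any(seg$start[-1L] < seg$end[-nrow(seg)])) {
    stop(what, ": overlapping segments within one stream")
  }
  invisible(seg)
}

#' Ward-style categorization of ground-truth and predicted events
#'
#' Each ground-truth event is Correct (C), Deleted (D: no overlapping
#' prediction), Fragmented (F: overlapped by two or more predictions),
#' Merged (M: some overlapping prediction also covers another ground-truth
#' event), or both (FM). Each predicted event is Correct, an Insertion (I':
#' overlaps no ground truth), Merging (M': overlaps two or more ground-truth
#' events), Fragmenting (F': its ground-truth event is fragmented), or both
#' (FM'). Overlap means sharing at least one frame. The two Correct tallies
#' agree by construction.
#'
#' @param gt,pred segment data.frames from [frames_to_events()] (same class).
#' @param min_overlap_frac optional minimum shared fraction of the shorter
#'   segment for two segments to count as overlapping (default 0: any shared
#'   frame).
#' @return named integer vector with elements
#'   `C, D, F, M, FM` (ground-truth side) and `Ip, Fp, Mp, FMp`
#'   (prediction side).
#' @export
categorize_events <- function(gt, pred, min_overlap_frac = 0) {
  check_segments(gt, "gt")
  check_segments(pred, "pred")
  ng <- nrow(gt)
  np <- nrow(pred)
  ov <- if (ng && np) {
    outer(seq_len(ng), seq_len(np), function(i, j)
      segments_overlap(gt$start[i], gt$end[i], pred$start[j], pred$end[j],
                       min_overlap_frac))
  } else matrix(FALSE, ng, np)
  gt_deg <- rowSums(ov)     # predictions overlapping each gt event
  pr_deg <- colSums(ov)     # gt events overlapping each prediction

  counts <- c(C = 0L, D = 0L, F = 0L, M = 0L, FM = 0L,
              Ip = 0L, Fp = 0L, Mp = 0L, FMp = 0L)
  for (i in seq_len(ng)) {
    if (gt_deg[i] == 0) { counts["D"] <- counts["D"] + 1L; next }
    frag <- gt_deg[i] >= 2
    merg <- any(pr_deg[ov[i, ]] >= 2)
    key <- if (frag && merg) "FM" else if (frag) "F"
           else if (merg) "M" else "C"
    counts[key] <- counts[key] + 1L
  }
  for (j in seq_len(np)) {
    if (pr_deg[j] == 0) { counts["Ip"] <- counts["Ip"] + 1L; next }
    merging <- pr_deg[j] >= 2
    fragging <- any(gt_deg[ov[, j]] >= 2)
    key <- if (merging && fragging) "FMp" else if (merging) "Mp"
           else if (fragging) "Fp" else NA
    if (!is.na(key)) counts[key] <- counts[key] + 1L
  }
  counts["C"] <- ng - counts["D"] - counts["F"] - counts["M"] - counts["FM"]
  pc <- np - counts["Ip"] - counts["Fp"] - counts["Mp"] - counts["FMp"]
  stopifnot(counts["C"] == pc)  # the two Correct tallies must agree
  counts
}

#' Event-level precision, recall and F1 from category counts
#'
#' `P = (C + M' + FM' + F') / (C + M' + FM' + F' + I')`,
#' `R = (C + F + FM + M) / (C + F + FM + M + D)`, and F1 their harmonic
#' mean. Fragmenting and merging returns count as positives: only pure
#' insertions hurt precision and only pure deletions hurt recall. When a
#' side has zero events its metric is 1 if the other side is also empty,
#' else 0.
#'
#' @param counts named vector from [categorize_events()] (or a sum of such).
#' @return named numeric vector `c(P, R, F1)`.
#' @export
event_prf <- function(counts) {
  counts <- counts[c("C", "D", "F", "M", "FM", "Ip", "Fp", "Mp", "FMp")]
  if (any(counts < 0)) stop("negative category counts")
  n_gt <- sum(counts[c("C", "D", "F", "M", "FM")])
  n_pred <- sum(counts[c("C", "Ip", "Fp", "Mp", "FMp")])
  P <- if (n_pred > 0) unname((n_pred - counts["Ip"]) / n_pred)
       else as.numeric(n_gt == 0)
  R <- if (n_gt > 0) unname((n_gt - counts["D"]) / n_gt)
       else as.numeric(n_pred == 0)
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

# Window-level macro precision/recall/F1 over the classes present in the
# ground truth or predictions (per-class metrics with empty denominators
# count as 0, as in the usual macro definition).
window_macro_metrics <- function(gt, pred) {
  classes <- union(unique(gt), unique(pred))
  per <- vapply(classes, function(cl) {
    tp <- sum(gt == cl & pred == cl)
    p <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    r <- if (sum(gt == cl) > 0) tp / sum(gt == cl) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3))
  c(P_macro = mean(per[1, ]), R_macro = mean(per[2, ]),
    F1_macro = mean(per[3, ]))
}

#' Score a prediction stream against ground truth
#'
#' Computes, for each activity class (the NULL background is not an event
#' class), the Ward category counts and event-level precision/recall/F1;
#' pooled event metrics obtained by summing category counts over classes
#' before applying the precision/recall formulas (micro pooling); a
#' macro-averaged set of the same metrics; and window-level macro
#' precision/recall/F1 over all classes including NULL.
#'
#' @param gt,pred [prediction_stream()]s (or plain label vectors) of equal
#'   length on the same stride.
#' @param classes activity classes to score (default [activity_classes()]).
#' @param min_overlap_frac passed to [categorize_events()].
#' @return list with elements `per_class` (data.frame), `pooled` (P, R, F1),
#'   `event_macro`, `window` (macro P/R/F1), and `counts` (summed category
#'   counts).
#' @export
score_streams <- function(gt, pred, classes = activity_classes(),
                          min_overlap_frac = 0) {
  g <- if (inherits(gt, "prediction_stream")) gt$labels else as.character(gt)
  p <- if (inherits(pred, "prediction_stream")) pred$labels
       else as.character(pred)
  if (length(g) != length(p)) stop("gt and pred length mismatch")
  per <- lapply(classes, function(cl) {
    counts <- categorize_events(frames_to_events(g, cl),
                                frames_to_events(p, cl), min_overlap_frac)
    c(counts, event_prf(counts))
  })
  tab <- do.call(rbind, lapply(per, function(x) as.data.frame(t(x))))
  tab <- cbind(class = classes, tab)
  total <- colSums(tab[, c("C", "D", "F", "M", "FM",
                           "Ip", "Fp", "Mp", "FMp")])
  scored <- tab$C + tab$D + tab$F + tab$M + tab$FM +
    tab$Ip + tab$Fp + tab$Mp + tab$FMp > 0
  list(per_class = tab,
       pooled = event_prf(total),
       event_macro = if (any(scored)) {
         c(P = mean(tab$P[scored]), R = mean(tab$R[scored]),
           F1 = mean(tab$F1[scored]))
       } else c(P = 1, R = 1, F1 = 1),
       window = window_macro_metrics(g, p),
       counts = total)
}
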