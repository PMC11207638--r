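#' Segment a stream into overlapping sliding windows
#'
#' Windows are half-open intervals `[start, start + window_s)` whose starts
#' are multiples of the stride `window_s * (1 - overlap)` from the stream
#' start; with the defaults (1 s windows, 75% overlap) the stride is 0.25 s.
#' The number of windows is `floor((T - window_s) / stride) + 1` for a stream
#' of duration `T >= window_s`, else 0.
#'
#' Each window carries an assigned label: the majority per-sample label, with
#' ties broken in favor of a non-NULL activity, and ties among activities
#' broken by the label at the window's center sample (falling back to
#' vocabulary order).
#'
#' @param stream a [sensor_stream()].
#' @param window_s window length in seconds (> 0).
#' @param overlap fractional overlap between consecutive windows, in `[0, 1)`.
#' @return object of class `adl_windows`: window anchors, per-window labels,
#'   and a reference to the stream samples.
#' @export
segment_windows <- function(stream, window_s = 1.0, overlap = 0.75) {
  stopifnot(inherits(stream, "sensor_stream"), window_s > 0,
            overlap >= 0, overlap < 1)
  rate <- stream$sample_rate_hz
  len <- round(window_s * rate)
  if (len < 2) stop("window too short for the sample rate")
  stride_s <- window_s * (1 - overlap)
  if (stride_s * rate < 1) stop("stride shorter than one sample; reduce overlap")
  n_samp <- nrow(stream$data)
  dur <- n_samp / rate
  # window starts at exact multiples of the stride; sample slices are
  # rounded per window so the count formula holds at any rate
  n_win <- if (dur < window_s) 0L
           else floor((dur - window_s) / stride_s + 1e-9) + 1L
  start_s <- (seq_len(n_win) - 1L) * stride_s
  starts <- as.integer(round(start_s * rate)) + 1L
  keep <- starts + len - 1L <= n_samp
  starts <- starts[keep]
  start_s <- start_s[keep]
  labels <- window_labels(stream$data$label, starts, len)
  structure(list(stream = stream, start_idx = starts, len = len,
                 window_s = window_s, stride_s = stride_s,
                 start_s = start_s, label = labels),
            class = "adl_windows")
}

#' @export
print.adl_windows <- function(x, ...) {
  cat(sprintf("<adl_windows> %d windows of %g s (stride %g s) over %.1f s\n",
              length(x$start_idx), x$window_s, x$stride_s,
              stream_duration_s(x$stream)))
  invisible(x)
}

#' @export
length.adl_windows <- function(x) length(x$start_idx)

# Majority label per window with the non-NULL / center-sample tie-break.
window_labels <- function(labels, starts, len) {
  if (!length(starts)) return(character(0))
  vocab <- label_vocabulary()
  codes <- match(labels, vocab)
  idx <- outer(starts, 0:(len - 1L), "+")
  counts <- vapply(seq_along(vocab),
                   function(k) rowSums(matrix(codes[idx] == k, nrow(idx))),
                   numeric(nrow(idx)))
  counts <- matrix(counts, nrow = nrow(idx))
  null_k <- match("NULL", vocab)
  center <- codes[starts + (len %/% 2L)]
  vapply(seq_along(starts), function(i) {
    ct <- counts[i, ]
    top <- which(ct == max(ct))
    if (length(top) > 1L && any(top != null_k)) top <- top[top != null_k]
    if (length(top) > 1L) {
      top <- if (center[i] %in% top) center[i] else top[1L]
    }
    vocab[top[1L]]
  }, character(1))
}

# Rasterize per-sample ground-truth labels onto the prediction grid using the
# same assignment rule as training windows.
#' Ground-truth label stream on the window grid
#'
#' Maps per-sample labels to one label per sliding window, using the window
#' label rule of [segment_windows()], so a ground-truth stream can be scored
#' against a prediction stream on the same grid.
#'
#' @inheritParams segment_windows
#' @return a [prediction_stream()].
#' @export
ground_truth_stream <- function(stream, window_s = 1.0, overlap = 0.75) {
  w <- segment_windows(stream, window_s, overlap)
  prediction_stream(w$label, stride_s = w$stride_s,
                    start_s = if (length(w$start_s)) w$start_s[1L] else 0)
}
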