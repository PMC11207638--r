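#' Ordered per-window prediction stream
#'
#' @param labels character vector of labels at fixed stride, in time order.
#' @param stride_s seconds between consecutive predictions (0.25 s for 1 s
#'   windows at 75% overlap).
#' @param start_s time of the first window start.
#' @return object of class `prediction_stream`.
#' @export
prediction_stream <- function(labels, stride_s = 0.25, start_s = 0) {
  stopifnot(stride_s > 0)
  structure(list(labels = as.character(labels), stride_s = stride_s,
                 start_s = start_s),
            class = "prediction_stream")
}

#' @export
length.prediction_stream <- function(x) length(x$labels)

#' @export
print.prediction_stream <- function(x, ...) {
  cat(sprintf("<prediction_stream> %d labels, stride %g s\n",
              length(x$labels), x$stride_s))
  invisible(x)
}

#' Distance-based voting weights
#'
#' The five weighting functions used by context-based correction, as
#' functions of the context size `ws` and the distance `d` from the window
#' center (with `h = ceiling(ws/2)`):
#' `W1 = max(h - d, 0)` (triangular), `W2 = 1/(d + 2)` (inverse),
#' `W3 = max(h - d, 0)^2` (squared), `W4 = log(max(h - d, 0) + 1)` (log),
#' `W5 = 1/log(d + 2)` (inverse log). Logs are natural by default; the
#' corrected label is invariant to the base. Negative triangular values at
#' extreme offsets are clamped to zero: votes accumulate evidence.
#'
#' @param fn one of `"W1" .. "W5"`.
#' @param ws context window size (count of predictions).
#' @param d non-negative distance(s) from the window center (vectorized).
#' @param log_base logarithm base for W4/W5.
#' @return numeric weight(s).
#' @export
weight_value <- function(fn, ws, d, log_base = exp(1)) {
  h <- ceiling(ws / 2)
  switch(fn,
         W1 = pmax(h - d, 0),
         W2 = 1 / (d + 2),
         W3 = pmax(h - d, 0)^2,
         W4 = log(pmax(h - d, 0) + 1, base = log_base),
         W5 = 1 / log(d + 2, base = log_base),
         stop("unknown weighting function: ", fn))
}

# Weight vector over positions 1..ws. Default distance is |i - midpoint|
# (symmetric, per the definition of d as distance from the window center);
# signed_d = TRUE reproduces the literal printed offset i - midpoint + 1,
# which is asymmetric.
position_weights <- function(fn, ws, log_base = exp(1), signed_d = FALSE) {
  midpoint <- ws %/% 2 + 1
  i <- seq_len(ws)
  d <- if (signed_d) i - midpoint + 1 else abs(i - midpoint)
  weight_value(fn, ws, d, log_base)
}

#' Correct a single prediction from its context window
#'
#' Every position in the context votes for its label with a weight that
#' decays with distance from the window midpoint (`floor(ws/2) + 1`); the
#' label with the highest score wins. Score ties are broken by the higher
#' raw label count in the window, remaining ties by earliest first
#' appearance.
#'
#' @param w character vector: the context window of labels.
#' @param fn weighting function id (`"W1" .. "W5"`).
#' @param log_base log base for W4/W5 (result is invariant to it).
#' @param signed_d use the literal signed offset instead of the symmetric
#'   distance (compatibility option).
#' @return the corrected label (length-1 character).
#' @export
correct_window <- function(w, fn = "W4", log_base = exp(1),
                           signed_d = FALSE) {
  ws <- length(w)
  if (ws == 0L) stop("empty context window")
  wt <- position_weights(fn, ws, log_base, signed_d)
  u <- unique(w)                      # first-appearance order
  score <- vapply(u, function(lab) sum(wt[w == lab]), 0)
  cnt <- vapply(u, function(lab) sum(w == lab), 0L)
  top <- which(score >= max(score) * (1 - 1e-9) - 1e-12)
  if (length(top) > 1L) top <- top[cnt[top] == max(cnt[top])]
  u[top[1L]]
}

#' Context-based correction of a prediction stream
#'
#' Replaces each prediction with the weighted-vote winner of the `ws`
#' predictions around it. In the default `"centered"` mode the context for
#' position `t` spans `[t - (midpoint - 1), t + (ws - midpoint)]`; positions
#' whose full context would fall outside the stream pass through unchanged,
#' and the output is aligned with the input (as event-level scoring against
#' ground truth requires). `"literal_streaming"` mode instead emits, after a
#' warm-up of `ws` pass-through outputs, the correction of the trailing
#' context window — the form a streaming deployment would use, with its
#' inherent lag.
#'
#' @param pred a [prediction_stream()].
#' @param fn weighting function id (`"W1" .. "W5"`).
#' @param ws_s context span in seconds (converted to a prediction count via
#'   the stream stride: `ws = round(ws_s / stride)`); alternatively give
#'   `ws_count` directly.
#' @param mode `"centered"` (default) or `"literal_streaming"`.
#' @param ws_count context size as a count, overriding `ws_s`.
#' @param log_base,signed_d passed to [correct_window()].
#' @return corrected [prediction_stream()] of the same length.
#' @export
correct_stream <- function(pred, fn = "W4", ws_s = 160,
                           mode = c("centered", "literal_streaming"),
                           ws_count = NULL, log_base = exp(1),
                           signed_d = FALSE) {
  stopifnot(inherits(pred, "prediction_stream"))
  mode <- match.arg(mode)
  p <- pred$labels
  n <- length(p)
  ws <- ws_count %||% max(1L, as.integer(round(ws_s / pred$stride_s)))
  if (ws < 1L) stop("context size must be >= 1")
  if (n == 0L || ws == 1L) return(pred)
  if (ws > n) {
    warning("context window (", ws, ") longer than the stream (", n,
            "); stream passed through unchanged")
    return(pred)
  }
  out <- p
  wt <- position_weights(fn, ws, log_base, signed_d)
  codes <- match(p, unique(p))
  ncl <- max(codes)
  if (mode == "centered") {
    midpoint <- ws %/% 2 + 1L
    left <- midpoint - 1L
    right <- ws - midpoint
    for (t in (left + 1L):(n - right)) {
      win <- (t - left):(t + right)
      cw <- codes[win]
      sc <- rowsum(wt, cw)
      top <- as.integer(rownames(sc))[
        which(sc >= max(sc) * (1 - 1e-9) - 1e-12)]
      if (length(top) > 1L) {
        cnt <- tabulate(cw, ncl)[top]
        top <- top[cnt == max(cnt)]
        if (length(top) > 1L) top <- top[which.min(match(top, cw))]
      }
      out[t] <- unique(p)[top[1L]]
    }
  } else {
    for (i in (ws + 1L):n) {
      out[i] <- correct_window(p[(i - ws):(i - 1L)], fn, log_base, signed_d)
    }
  }
  prediction_stream(out, pred$stride_s, pred$start_s)
}
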