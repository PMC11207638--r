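#' Construct a dual-wrist sensor stream
#'
#' A sensor stream holds uniformly sampled, per-sample-labeled dual-wrist
#' accelerometer (and optionally gyroscope) data. Channel columns are named
#' `<hand>_<axis>` with hand in `left`/`right` and axis in
#' `ax, ay, az[, gx, gy, gz]`.
#'
#' @param data data.frame with column `t` (seconds, uniform grid), the
#'   channel columns, and `label` (closed vocabulary).
#' @param participant participant identifier.
#' @param sample_rate_hz sampling rate in Hz.
#' @param session session identifier (participants may contribute several).
#' @param validate check invariants (uniform grid, vocabulary, channels).
#' @return object of class `sensor_stream`.
#' @export
sensor_stream <- function(data, participant, sample_rate_hz,
                          session = paste0(participant, "-1"),
                          validate = TRUE) {
  stopifnot(is.data.frame(data), sample_rate_hz > 0)
  if (validate) {
    need <- c("t", "label")
    miss <- setdiff(need, names(data))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    if (nrow(data) == 0L) stop("no samples")
    bad <- setdiff(unique(as.character(data$label)), label_vocabulary())
    if (length(bad)) stop("labels outside the closed vocabulary: ",
                          paste(bad, collapse = ", "))
    if (nrow(data) > 1L) {
      dt <- diff(data$t)
      if (any(dt <= 0)) stop("timestamps must be strictly increasing")
      if (max(abs(dt - 1 / sample_rate_hz)) > 0.25 / sample_rate_hz) {
        stop("timestamps not uniform at the declared rate; resample first")
      }
    }
  }
  structure(list(data = data, participant = as.character(participant),
                 session = as.character(session),
                 sample_rate_hz = sample_rate_hz),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  tab <- table(x$data$label)
  cat(sprintf("<sensor_stream> participant=%s session=%s  %d samples @ %g Hz (%.2f h)\n",
              x$participant, x$session, nrow(x$data), x$sample_rate_hz,
              nrow(x$data) / x$sample_rate_hz / 3600))
  cat("  channels:", paste(stream_channels(x), collapse = " "), "\n")
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

stream_channels <- function(stream) {
  setdiff(names(stream$data), c("t", "label"))
}

#' Duration of a stream in seconds
#' @param stream a `sensor_stream`.
#' @export
stream_duration_s <- function(stream) nrow(stream$data) / stream$sample_rate_hz

# Channel columns required for feature extraction (dual-wrist accelerometer).
accel_channels <- function() {
  as.vector(outer(c("left", "right"), c("ax", "ay", "az"),
                  function(h, a) paste(h, a, sep = "_")))
}

#' Load a labeled sensor stream from CSV
#'
#' Reads one or more long-format CSV files (columns `t`, `ax`, `ay`, `az`
#' \[, `gx`, `gy`, `gz`\], `label`, `hand`, `participant`; one row per sample
#' per hand), applies the relabeling policy, and resamples every channel onto
#' a uniform grid at `sample_rate_hz` by linear interpolation (labels by
#' previous-value interpolation). Both hands must be present.
#'
#' @param paths CSV file path(s), jointly covering both hands of one session.
#' @param relabel named raw-to-canonical label map.
#' @param sample_rate_hz target uniform rate (Hz).
#' @param session session identifier; default derived from the participant.
#' @return a [sensor_stream()].
#' @export
load_stream <- function(paths, relabel = default_relabel_map(),
                        sample_rate_hz = 50, session = NULL) {
  raw <- do.call(rbind, lapply(paths, function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("t", "ax", "ay", "az", "label", "hand", "participant")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing required column(s) in ", p, ": ",
                           paste(miss, collapse = ", "))
    d
  }))
  if (nrow(raw) == 0L) stop("no samples")
  participant <- unique(raw$participant)
  if (length(participant) != 1L) stop("multiple participants in one stream")
  hands <- sort(unique(raw$hand))
  if (!identical(hands, c("left", "right"))) {
    stop("both hands required; found: ", paste(hands, collapse = ", "))
  }
  raw$label <- apply_relabel(raw$label, relabel)
  axes <- intersect(c("ax", "ay", "az", "gx", "gy", "gz"), names(raw))

  per_hand <- lapply(c("left", "right"), function(h) {
    d <- raw[raw$hand == h, , drop = FALSE]
    d <- d[order(d$t), , drop = FALSE]
    dt <- diff(d$t)
    if (any(dt < 0)) stop("non-monotone timestamps for hand ", h)
    d[!duplicated(d$t), , drop = FALSE]
  })
  t0 <- max(vapply(per_hand, function(d) min(d$t), 0))
  t1 <- min(vapply(per_hand, function(d) max(d$t), 0))
  if (t1 - t0 <= 0) stop("hands do not overlap in time")
  grid <- seq(t0, t1, by = 1 / sample_rate_hz)

  out <- data.frame(t = grid - t0)
  for (i in seq_along(per_hand)) {
    h <- c("left", "right")[i]
    d <- per_hand[[i]]
    for (a in axes) {
      out[[paste(h, a, sep = "_")]] <-
        stats::approx(d$t, d[[a]], xout = grid, rule = 2)$y
    }
  }
  # labels from the left-hand annotation track (both hands share one app label)
  dl <- per_hand[[1L]]
  lab_idx <- stats::approx(dl$t, seq_len(nrow(dl)), xout = grid,
                           method = "constant", f = 0, rule = 2)$y
  out$label <- dl$label[lab_idx]
  sensor_stream(out, participant, sample_rate_hz,
                session = session %||% paste0(participant, "-1"))
}

#' Write a sensor stream to long-format CSV
#'
#' Inverse of [load_stream()]: one row per sample per hand.
#' @param stream a `sensor_stream`.
#' @param path output CSV path.
#' @export
write_stream_csv <- function(stream, path) {
  d <- stream$data
  axes <- unique(sub("^(left|right)_", "", stream_channels(stream)))
  rows <- lapply(c("left", "right"), function(h) {
    block <- data.frame(t = d$t)
    for (a in axes) block[[a]] <- d[[paste(h, a, sep = "_")]]
    block$label <- d$label
    block$hand <- h
    block$participant <- stream$participant
    block
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
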