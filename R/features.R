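#' Spectral centroid, spread, and rolloff of a magnitude spectrum
#'
#' Operates on one-sided DFT magnitudes `X(k)`, `k = 1..N`, DC excluded.
#' The centroid is `sum(k X(k)) / sum(X(k))`; the spread is the square root
#' of the X-weighted second moment about the centroid; the rolloff is the
#' smallest bin `k` such that the cumulative magnitude up to `k` reaches
#' `rolloff_frac` of the total. An all-zero spectrum returns
#' `centroid = spread = 0, rolloff = 1` rather than NaN.
#'
#' @param x numeric vector of non-negative magnitudes (bin 1..N).
#' @param rolloff_frac cumulative-magnitude fraction for the rolloff
#'   (default 0.85).
#' @return named numeric vector `c(centroid, spread, rolloff)`.
#' @export
spectral_summary <- function(x, rolloff_frac = 0.85) {
  stopifnot(is.numeric(x), length(x) >= 1, all(x >= 0))
  tot <- sum(x)
  if (tot <= 0) return(c(centroid = 0, spread = 0, rolloff = 1))
  k <- seq_along(x)
  ctr <- sum(k * x) / tot
  spr <- sqrt(sum((k - ctr)^2 * x) / tot)
  roll <- which(cumsum(x) >= rolloff_frac * tot)[1L]
  c(centroid = ctr, spread = spr, rolloff = roll)
}

#' Box-counting fractal dimension of a signal
#'
#' Rescales the curve (index, value) to the unit square, counts the boxes
#' `N(eps)` of side `eps = 2^-j` intersected by the sampled trace over a
#' dyadic grid of scales, and estimates the dimension as the slope of
#' `log N(eps)` against `log(1/eps)`. The estimate is clamped to `[1, 2]`;
#' constant or too-short (< 8 samples) signals return 1 by convention.
#'
#' @param x numeric signal.
#' @return fractal dimension estimate in `[1, 2]`.
#' @export
fractal_dimension <- function(x) {
  n <- length(x)
  if (n < 8L || !all(is.finite(x))) return(1)
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(1)
  u <- (x - rng[1]) / (rng[2] - rng[1])     # values in [0,1]
  tt <- (seq_len(n) - 1) / (n - 1)          # time in [0,1]
  jmax <- max(2L, floor(log2(n / 2)))
  m <- 2^(1:jmax)
  logN <- vapply(m, function(mm) {
    col <- pmin(floor(tt * mm), mm - 1L)
    lo <- tapply(u, col, min)
    hi <- tapply(u, col, max)
    log(sum(floor(hi * mm - 1e-9) - floor(lo * mm) + 1))
  }, 0)
  slope <- stats::coef(stats::lm(logN ~ log(m)))[2L]
  min(max(unname(slope), 1), 2)
}

# Local maxima with prominence >= min_prom. The prominence of a peak is its
# height above the higher of the two minima separating it from neighboring
# terrain at least as high (window edges act as terrain).
find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(cand) || min_prom <= 0) {
    return(if (min_prom <= 0) cand else integer(0))
  }
  keep <- vapply(cand, function(i) {
    j <- i - 1L
    left <- x[i]
    while (j >= 1L && x[j] <= x[i]) { left <- min(left, x[j]); j <- j - 1L }
    j <- i + 1L
    right <- x[i]
    while (j <= n && x[j] <= x[i]) { right <- min(right, x[j]); j <- j + 1L }
    (x[i] - max(left, right)) >= min_prom
  }, logical(1))
  cand[keep]
}

# Feature short names, per accelerometer axis (17) and per hand (2).
axis_feature_names <- function() {
  c("jerk", "peak_height_mean", "peak_height_sd", "energy", "entropy",
    "mean", "sd", "rms", "n_peaks", "peaks_q_mean", "peaks_q_sd",
    "n_valleys", "valleys_q_mean", "valleys_q_sd",
    "spec_centroid", "spec_spread", "spec_rolloff")
}
hand_feature_names <- function() c("axis_overlap", "fractal_dim")

#' Names of the 106 window features
#'
#' 17 time/frequency features per accelerometer axis per hand
#' (\eqn{17 \times 3 \times 2 = 102}) plus axis overlap and fractal dimension
#' per hand (\eqn{2 \times 2 = 4}).
#' @return character vector of length 106.
#' @export
feature_names <- function() {
  per_axis <- as.vector(vapply(accel_channels(), function(ch)
    paste(ch, axis_feature_names(), sep = "_"), character(17)))
  per_hand <- as.vector(vapply(c("left", "right"), function(h)
    paste(h, hand_feature_names(), sep = "_"), character(2)))
  c(per_axis, per_hand)
}

#' Extract the 106-feature window representation
#'
#' Computes, for every window, 17 features per accelerometer axis per hand —
#' average jerk (mean absolute first difference times the sample rate), mean
#' and standard deviation of peak heights, energy (mean squared deviation
#' from the window mean), spectral entropy, mean, standard deviation, RMS,
#' peak and valley counts with their per-quarter mean and standard deviation,
#' and spectral centroid / spread / rolloff — plus two per-hand features:
#' axis overlap (pairwise axis-trace crossings per second) and the
#' box-counting fractal dimension of the acceleration-norm trace. Peaks and
#' valleys are local extrema with prominence at least 0.1 times the window
#' standard deviation; spectra are one-sided DFT magnitudes with the DC bin
#' excluded.
#'
#' @param windows an [segment_windows()] result (dual-wrist accelerometer
#'   channels required).
#' @param rolloff_frac spectral rolloff fraction (default 0.85).
#' @return data.frame of class `adl_features`: `window_start_s`,
#'   `window_end_s`, `label`, then the 106 feature columns of
#'   [feature_names()]. Carries the stride as attribute `stride_s`.
#' @export
extract_features <- function(windows, rolloff_frac = 0.85) {
  stopifnot(inherits(windows, "adl_windows"))
  stream <- windows$stream
  miss <- setdiff(accel_channels(), stream_channels(stream))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  n <- length(windows$start_idx)
  L <- windows$len
  rate <- stream$sample_rate_hz
  fnames <- feature_names()
  out <- matrix(NA_real_, n, length(fnames), dimnames = list(NULL, fnames))
  meta <- data.frame(window_start_s = windows$start_s,
                     window_end_s = windows$start_s + windows$window_s,
                     label = windows$label, stringsAsFactors = FALSE)
  if (n == 0L) {
    res <- cbind(meta, as.data.frame(out))
    return(as_adl_features(res, windows$stride_s))
  }
  idx <- outer(windows$start_idx, 0:(L - 1L), "+")
  qid <- ceiling(4 * seq_len(L) / L)  # four equal non-overlapping quarters
  kbins <- seq_len(L %/% 2)

  chans <- lapply(accel_channels(), function(ch) {
    matrix(stream$data[[ch]][idx], n, L)
  })
  names(chans) <- accel_channels()

  for (ch in accel_channels()) {
    M <- chans[[ch]]
    mu <- rowMeans(M)
    msq <- rowMeans(M^2)
    sdv <- sqrt(pmax(rowSums((M - mu)^2) / (L - 1), 0))
    out[, paste0(ch, "_mean")] <- mu
    out[, paste0(ch, "_sd")] <- sdv
    out[, paste0(ch, "_rms")] <- sqrt(msq)
    out[, paste0(ch, "_energy")] <- pmax(msq - mu^2, 0)
    out[, paste0(ch, "_jerk")] <-
      rowMeans(abs(M[, -1L, drop = FALSE] - M[, -L, drop = FALSE])) * rate

    # one-sided DFT magnitudes, DC excluded (bins 1..floor(L/2))
    mag <- Mod(stats::mvfft(t(M)))[1L + kbins, , drop = FALSE]
    tot <- colSums(mag)
    # guard against FFT round-off on (near-)constant windows: spectral mass
    # below ~1e-9 of the signal mass is numerical zero
    pos <- tot > 1e-9 * pmax(rowSums(abs(M)), .Machine$double.xmin)
    ctr <- spr <- ent <- numeric(n)
    roll <- rep(1, n)
    if (any(pos)) {
      mp <- mag[, pos, drop = FALSE]
      tp <- tot[pos]
      ctr[pos] <- colSums(kbins * mp) / tp
      spr[pos] <- sqrt(colSums((outer(kbins, ctr[pos], "-"))^2 * mp) / tp)
      p <- sweep(mp, 2, tp, "/")
      plogp <- p * log(p)
      plogp[p == 0] <- 0
      ent[pos] <- -colSums(plogp)
      cs <- apply(mp, 2, cumsum)
      cs <- matrix(cs, nrow = length(kbins))
      roll[pos] <- apply(cs >= rep(rolloff_frac * tp, each = length(kbins)),
                         2, which.max)
    }
    out[, paste0(ch, "_spec_centroid")] <- ctr
    out[, paste0(ch, "_spec_spread")] <- spr
    out[, paste0(ch, "_spec_rolloff")] <- roll
    out[, paste0(ch, "_entropy")] <- ent

    # peak / valley family (prominence rule)
    pk <- matrix(0, n, 8)
    for (i in seq_len(n)) {
      x <- M[i, ]
      thr <- 0.1 * sdv[i]
      if (sdv[i] > 0) {
        p_i <- find_peaks(x, thr)
        v_i <- find_peaks(-x, thr)
        if (length(p_i)) {
          qc <- tabulate(qid[p_i], 4)
          pk[i, 1:4] <- c(length(p_i), mean(x[p_i]),
                          if (length(p_i) > 1) stats::sd(x[p_i]) else 0,
                          0)
          pk[i, 4] <- mean(qc)
          pk[i, 5] <- stats::sd(qc)
        }
        if (length(v_i)) {
          qc <- tabulate(qid[v_i], 4)
          pk[i, 6:8] <- c(length(v_i), mean(qc), stats::sd(qc))
        }
      }
    }
    out[, paste0(ch, "_n_peaks")] <- pk[, 1]
    out[, paste0(ch, "_peak_height_mean")] <- pk[, 2]
    out[, paste0(ch, "_peak_height_sd")] <- pk[, 3]
    out[, paste0(ch, "_peaks_q_mean")] <- pk[, 4]
    out[, paste0(ch, "_peaks_q_sd")] <- pk[, 5]
    out[, paste0(ch, "_n_valleys")] <- pk[, 6]
    out[, paste0(ch, "_valleys_q_mean")] <- pk[, 7]
    out[, paste0(ch, "_valleys_q_sd")] <- pk[, 8]
  }

  for (h in c("left", "right")) {
    ax <- chans[[paste0(h, "_ax")]]
    ay <- chans[[paste0(h, "_ay")]]
    az <- chans[[paste0(h, "_az")]]
    cross <- function(a, b) {
      d <- a - b
      rowSums(d[, -L, drop = FALSE] * d[, -1L, drop = FALSE] < 0)
    }
    out[, paste0(h, "_axis_overlap")] <-
      (cross(ax, ay) + cross(ax, az) + cross(ay, az)) / windows$window_s
    nrm <- sqrt(ax^2 + ay^2 + az^2)
    out[, paste0(h, "_fractal_dim")] <-
      vapply(seq_len(n), function(i) fractal_dimension(nrm[i, ]), 0)
  }

  stopifnot(all(is.finite(out)))
  as_adl_features(cbind(meta, as.data.frame(out)), windows$stride_s)
}

as_adl_features <- function(df, stride_s) {
  attr(df, "stride_s") <- stride_s
  class(df) <- c("adl_features", "data.frame")
  df
}

# Feature columns of an adl_features data.frame, in schema order.
feature_matrix <- function(features) {
  as.matrix(features[, feature_names(), drop = FALSE])
}

#' Extract features from a stream in one call
#'
#' Convenience wrapper: [segment_windows()] then [extract_features()].
#' @inheritParams segment_windows
#' @inheritParams extract_features
#' @export
stream_features <- function(stream, window_s = 1.0, overlap = 0.75,
                            rolloff_frac = 0.85) {
  extract_features(segment_windows(stream, window_s, overlap), rolloff_frac)
}
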