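# Independent brute-force oracles, deliberately written with plain loops and
# set operations so they share no code path with the implementation.

# Spectral centroid/spread/rolloff by explicit bin loops.
brute_spectral <- function(x, frac = 0.85) {
  tot <- 0
  for (v in x) tot <- tot + v
  num <- 0
  for (k in seq_along(x)) num <- num + k * x[k]
  ctr <- num / tot
  acc <- 0
  for (k in seq_along(x)) acc <- acc + (k - ctr)^2 * x[k]
  spr <- sqrt(acc / tot)
  run <- 0
  roll <- length(x)
  for (k in seq_along(x)) {
    run <- run + x[k]
    if (run >= frac * tot) { roll <- k; break }
  }
  c(centroid = ctr, spread = spr, rolloff = roll)
}

# Context correction by explicit per-label, per-position scoring.
brute_correct_window <- function(w, fn, log_base = exp(1)) {
  ws <- length(w)
  midpoint <- floor(ws / 2) + 1
  h <- ceiling(ws / 2)
  wt_of <- function(d) {
    switch(fn,
           W1 = max(h - d, 0),
           W2 = 1 / (d + 2),
           W3 = max(h - d, 0)^2,
           W4 = log(max(h - d, 0) + 1, base = log_base),
           W5 = 1 / log(d + 2, base = log_base))
  }
  labs <- unique(w)
  score <- numeric(length(labs))
  count <- integer(length(labs))
  for (i in seq_len(ws)) {
    li <- match(w[i], labs)
    score[li] <- score[li] + wt_of(abs(i - midpoint))
    count[li] <- count[li] + 1L
  }
  best <- NULL
  for (li in seq_along(labs)) {
    if (is.null(best)) { best <- li; next }
    if (score[li] > score[best] + 1e-9) best <- li
    else if (abs(score[li] - score[best]) <= 1e-9 &&
             count[li] > count[best]) best <- li
  }
  labs[best]
}

# Ward categories via frame-set intersections.
brute_categorize <- function(gt, pred) {
  gsets <- lapply(seq_len(nrow(gt)), function(i) seq(gt$start[i], gt$end[i] - 1))
  psets <- lapply(seq_len(nrow(pred)),
                  function(j) seq(pred$start[j], pred$end[j] - 1))
  hits <- function(a, bs) which(vapply(bs, function(b)
    length(intersect(a, b)) > 0, TRUE))
  out <- c(C = 0L, D = 0L, F = 0L, M = 0L, FM = 0L,
           Ip = 0L, Fp = 0L, Mp = 0L, FMp = 0L)
  for (i in seq_along(gsets)) {
    ov <- hits(gsets[[i]], psets)
    if (!length(ov)) { out["D"] <- out["D"] + 1L; next }
    frag <- length(ov) >= 2
    merg <- any(vapply(ov, function(j)
      length(hits(psets[[j]], gsets)) >= 2, TRUE))
    k <- if (frag && merg) "FM" else if (frag) "F" else if (merg) "M" else "C"
    out[k] <- out[k] + 1L
  }
  for (j in seq_along(psets)) {
    ov <- hits(psets[[j]], gsets)
    if (!length(ov)) { out["Ip"] <- out["Ip"] + 1L; next }
    merging <- length(ov) >= 2
    fragging <- any(vapply(ov, function(i)
      length(hits(gsets[[i]], psets)) >= 2, TRUE))
    if (merging && fragging) out["FMp"] <- out["FMp"] + 1L
    else if (merging) out["Mp"] <- out["Mp"] + 1L
    else if (fragging) out["Fp"] <- out["Fp"] + 1L
  }
  out
}

# All label streams of length n over the given alphabet.
enumerate_streams <- function(n, alphabet) {
  g <- do.call(expand.grid, c(rep(list(alphabet), n),
                              stringsAsFactors = FALSE))
  lapply(seq_len(nrow(g)), function(i) as.character(unlist(g[i, ])))
}
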