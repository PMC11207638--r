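# Fixtures built in code; expensive ones are computed once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small deterministic dual-wrist stream: sinusoid activity segments on a
# noisy NULL background. duration_s at integer-stride rates keeps window
# arithmetic exact.
toy_stream <- function(duration_s = 60, rate = 20, seed = 42,
                       events = data.frame(
                         class = c("Walking", "Drinking"),
                         start = c(10, 40), end = c(25, 46),
                         freq = c(2.0, 1.1), amp = c(2.5, 1.5))) {
  n <- duration_s * rate
  set.seed(seed)
  d <- data.frame(t = (seq_len(n) - 1) / rate)
  for (ch in c("left_ax", "left_ay", "left_az",
               "right_ax", "right_ay", "right_az")) {
    d[[ch]] <- rnorm(n, sd = 0.25)
  }
  lab <- rep("NULL", n)
  for (k in seq_len(nrow(events))) {
    i0 <- events$start[k] * rate + 1
    i1 <- min(events$end[k] * rate, n)
    if (i0 > n) next
    tt <- d$t[i0:i1]
    for (ch in c("right_ax", "right_ay", "right_az")) {
      d[[ch]][i0:i1] <- d[[ch]][i0:i1] +
        events$amp[k] * sin(2 * pi * events$freq[k] * tt)
    }
    lab[i0:i1] <- events$class[k]
  }
  d$label <- lab
  sensor_stream(d, participant = "T01", sample_rate_hz = rate)
}

# Synthetic adl_features with class-dependent Gaussian feature shifts; cheap
# stand-in for real extraction in model/imbalance tests.
fake_features <- function(counts, seed = 1, sep = 3) {
  set.seed(seed)
  classes <- names(counts)
  n <- sum(counts)
  X <- matrix(rnorm(n * 106), n, 106, dimnames = list(NULL, feature_names()))
  lab <- rep(classes, counts)
  for (k in seq_along(classes)) {
    rows <- lab == classes[k]
    cols <- ((k - 1) * 5 + 1):((k - 1) * 5 + 5)
    X[rows, cols] <- X[rows, cols] + sep
  }
  df <- cbind(data.frame(window_start_s = (seq_len(n) - 1) * 0.25,
                         window_end_s = (seq_len(n) - 1) * 0.25 + 1,
                         label = lab, stringsAsFactors = FALSE),
              as.data.frame(X))
  attr(df, "stride_s") <- 0.25
  class(df) <- c("adl_features", "data.frame")
  df
}

random_label_stream <- function(n, alphabet = c("A", "B", "NULL"),
                                p = c(0.1, 0.1, 0.8)) {
  sample(alphabet, n, replace = TRUE, prob = p)
}

# Reduced-scale signature tables for the end-to-end worlds: the default
# per-class oscillation frequencies and amplitudes, with event durations and
# rates rescaled so that short recordings still contain a few events of
# every class while staying NULL-dominated (~85% NULL).
scaled_signatures <- function(dur_mean_s, events_per_hour, amp_scale = 1) {
  sig <- default_signatures()
  sig$dur_mean_s <- dur_mean_s
  sig$events_per_hour <- events_per_hour
  sig$amp <- sig$amp * amp_scale
  sig
}

build_world <- function(cfg) {
  streams <- generate_dataset(cfg)
  feats <- lapply(streams, stream_features)
  list(cfg = cfg, streams = streams, feats = feats,
       gts = lapply(feats, function(f)
         prediction_stream(as.character(f$label), 0.25)))
}

# Clean world with well-separated signatures: pipeline-recovery checks.
e2e_world <- function() {
  cached("e2e_world", build_world(sim_config(
    participants = 4, hours = 0.75, sample_rate_hz = 20,
    signatures = scaled_signatures(
      dur_mean_s = c(60, 45, 20, 90, 30, 75, 40),
      events_per_hour = rep(1.5, 7)),
    seed = 20)))
}

# Harder world in which the window classifier misses rare events: activity
# amplitudes are scaled down to the background-noise level so that minority
# windows overlap the NULL class and the majority prior suppresses them;
# events are long enough that a 160 s correction context is informative.
# Train on the first three participants, evaluate pooled over the last two.
noisy_world <- function() {
  cached("noisy_world", build_world(sim_config(
    participants = 5, hours = 1.0, sample_rate_hz = 20,
    signatures = scaled_signatures(
      dur_mean_s = c(150, 120, 100, 200, 110, 160, 130),
      events_per_hour = rep(0.7, 7), amp_scale = 0.4),
    noise_sd = 0.6, signal_noise_sd = 0.6,
    distractor_rate_per_hour = 20, distractor_dur_s = 10,
    distractor_amp = 1.0,
    seed = 30)))
}

# Sum per-class category counts over several scored stream pairs and return
# pooled event metrics with the summed counts.
pooled_over <- function(gts, preds) {
  total <- NULL
  for (i in seq_along(gts)) {
    sc <- score_streams(gts[[i]], preds[[i]])
    total <- if (is.null(total)) sc$counts else total + sc$counts
  }
  list(metrics = event_prf(total), counts = total)
}

rbind_features <- function(lst) {
  out <- do.call(rbind, lapply(lst, as.data.frame))
  attr(out, "stride_s") <- attr(lst[[1]], "stride_s")
  class(out) <- c("adl_features", "data.frame")
  out
}
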