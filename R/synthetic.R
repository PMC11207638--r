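#' Default activity signatures for the synthetic generator
#'
#' One oscillatory signature per activity class: a dominant-hand sinusoid at
#' a class-specific frequency with class-specific amplitude, a log-normal
#' event-duration distribution, and a Poisson events-per-hour rate. The
#' default rates and durations are tuned so that the generated per-class
#' imbalance ratios fall in roughly `[40, 520]`, matching the magnitude
#' observed in in-the-wild ADL recordings (short self-care events embedded
#' sparsely in a long NULL background). Signatures are deliberately
#' idealized: their job is to exercise the pipeline and the imbalance
#' structure, not biomechanical realism.
#'
#' @return data.frame with columns `class`, `freq_hz`, `amp`, `two_handed`,
#'   `dur_mean_s`, `dur_sdlog`, `events_per_hour`.
#' @export
default_signatures <- function() {
  data.frame(
    class = activity_classes(),
    freq_hz = c(4.5, 3.2, 1.1, 1.7, 2.4, 2.0, 3.8),
    amp = c(3.0, 2.5, 1.5, 1.8, 2.0, 2.8, 2.6),
    two_handed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    dur_mean_s = c(120, 45, 12, 240, 25, 90, 30),
    dur_sdlog = rep(0.3, 7),
    events_per_hour = c(0.06, 0.175, 0.59, 0.30, 0.39, 0.87, 0.50),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic dual-wrist streams
#'
#' @param participants number of synthetic participants.
#' @param hours recording hours per participant: a single value, or a
#'   `c(min, max)` range sampled uniformly per participant. The default
#'   mirrors an in-the-wild study design of nine participants recording
#'   between 3 and 12 hours each.
#' @param sample_rate_hz accelerometer sampling rate.
#' @param signatures per-class signature table (see [default_signatures()]).
#' @param rate_multiplier scales every class's events-per-hour rate (useful
#'   for short simulations where rare classes would otherwise not occur).
#' @param noise_sd NULL-background accelerometer noise, m/s^2.
#' @param signal_noise_sd extra noise added on top of activity signatures.
#' @param distractor_rate_per_hour rate of unlabeled distractor motions in
#'   the background (they stay labeled NULL).
#' @param distractor_amp,distractor_dur_s distractor burst amplitude and
#'   mean duration.
#' @param seed master RNG seed; per-participant seeds are derived from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(participants = 9, hours = c(3, 12),
                       sample_rate_hz = 50,
                       signatures = default_signatures(),
                       rate_multiplier = 1,
                       noise_sd = 0.3, signal_noise_sd = 0.3,
                       distractor_rate_per_hour = 6,
                       distractor_amp = 1.5, distractor_dur_s = 8,
                       seed = 1) {
  stopifnot(participants >= 1, all(hours > 0), sample_rate_hz > 0)
  structure(list(participants = participants, hours = hours,
                 sample_rate_hz = sample_rate_hz, signatures = signatures,
                 rate_multiplier = rate_multiplier, noise_sd = noise_sd,
                 signal_noise_sd = signal_noise_sd,
                 distractor_rate_per_hour = distractor_rate_per_hour,
                 distractor_amp = distractor_amp,
                 distractor_dur_s = distractor_dur_s, seed = seed),
            class = "sim_config")
}

# Place n_ev non-overlapping events of the given durations uniformly in
# [0, T]; rejection sampling with a retry cap, dropping events that do not
# fit.
place_events <- function(placed, durations, T, gap_s = 2) {
  for (dur in durations) {
    if (dur >= T) next
    ok <- FALSE
    for (try in 1:200) {
      s <- stats::runif(1, 0, T - dur)
      e <- s + dur
      if (!nrow(placed) ||
          all(e + gap_s <= placed$start | s >= placed$end + gap_s)) {
        ok <- TRUE
        break
      }
    }
    if (ok) placed <- rbind(placed, data.frame(start = s, end = e))
  }
  placed[order(placed$start), , drop = FALSE]
}

# Render a sinusoidal burst onto the 3 axes of one hand.
render_burst <- function(data, hand, i0, i1, freq, amp, rate, phase,
                         axis_w) {
  tt <- (i0:i1) / rate
  for (a in 1:3) {
    col <- paste(hand, c("ax", "ay", "az")[a], sep = "_")
    data[i0:i1, col] <- data[i0:i1, col] +
      amp * axis_w[a] * sin(2 * pi * freq * tt + phase[a])
  }
  data
}

generate_stream <- function(cfg, participant_id, hours, seed) {
  rate <- cfg$sample_rate_hz
  n <- round(hours * 3600 * rate)
  T <- n / rate
  sig <- cfg$signatures
  with_seed(seed, {
    chan <- accel_channels()
    data <- as.data.frame(matrix(stats::rnorm(n * 6, sd = cfg$noise_sd),
                                 n, 6, dimnames = list(NULL, chan)))
    data <- cbind(t = (seq_len(n) - 1) / rate, data)
    labels <- rep("NULL", n)

    # unlabeled distractor motions in the background
    n_dist <- stats::rpois(1, cfg$distractor_rate_per_hour * hours)
    for (k in seq_len(n_dist)) {
      dur <- stats::rlnorm(1, log(cfg$distractor_dur_s) - 0.125, 0.5)
      s <- stats::runif(1, 0, max(T - dur, 0.1))
      i0 <- max(1, round(s * rate)); i1 <- min(n, round((s + dur) * rate))
      data <- render_burst(data, sample(c("left", "right"), 1), i0, i1,
                           stats::runif(1, 0.8, 4.8), cfg$distractor_amp,
                           rate, stats::runif(3, 0, 2 * pi),
                           abs(stats::rnorm(3, 0.6, 0.3)))
    }

    # activity events: Poisson placement, non-overlapping across classes
    placed <- data.frame(start = numeric(0), end = numeric(0))
    events <- data.frame(class = character(0), start = numeric(0),
                         end = numeric(0))
    for (r in seq_len(nrow(sig))) {
      n_ev <- stats::rpois(1, sig$events_per_hour[r] *
                              cfg$rate_multiplier * hours)
      if (n_ev == 0) next
      durs <- stats::rlnorm(n_ev,
                            log(sig$dur_mean_s[r]) - sig$dur_sdlog[r]^2 / 2,
                            sig$dur_sdlog[r])
      before <- nrow(placed)
      placed <- place_events(placed, durs, T)
      new <- placed[!(placed$start %in% events$start), , drop = FALSE]
      if (nrow(new)) {
        events <- rbind(events, cbind(class = sig$class[r], new))
      }
    }
    # fixed per-class axis mix so each class has a stable direction pattern
    axis_mix <- function(r) {
      c(0.9, 0.55, 0.3)[1 + ((r + 0:2) %% 3)]
    }
    for (k in seq_len(nrow(events))) {
      r <- match(events$class[k], sig$class)
      i0 <- max(1, round(events$start[k] * rate))
      i1 <- min(n, round(events$end[k] * rate))
      phase <- stats::runif(3, 0, 2 * pi)
      data <- render_burst(data, "right", i0, i1, sig$freq_hz[r],
                           sig$amp[r], rate, phase, axis_mix(r))
      off_amp <- if (sig$two_handed[r]) sig$amp[r] else 0.3 * sig$amp[r]
      data <- render_burst(data, "left", i0, i1, sig$freq_hz[r], off_amp,
                           rate, stats::runif(3, 0, 2 * pi), axis_mix(r))
      if (cfg$signal_noise_sd > 0) {
        idx <- i0:i1
        data[idx, chan] <- data[idx, chan] +
          matrix(stats::rnorm(length(idx) * 6, sd = cfg$signal_noise_sd),
                 length(idx), 6)
      }
      labels[i0:i1] <- events$class[k]
    }
    data$label <- labels
    sensor_stream(data, participant_id, rate)
  })
}

#' Generate a synthetic labeled dataset
#'
#' One continuous dual-wrist stream per participant: a NULL background of
#' low-amplitude noise with unlabeled distractor motions, into which labeled
#' activity events are placed by a per-class Poisson process and rendered as
#' the class's oscillatory signature (dominant right hand; both hands for
#' two-handed classes). Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list of [sensor_stream()]s with a `manifest` attribute
#'   (per-class hours and achieved imbalance ratios, pooled over streams).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  hours <- with_seed(cfg$seed, {
    if (length(cfg$hours) == 2L) {
      stats::runif(cfg$participants, cfg$hours[1], cfg$hours[2])
    } else rep(cfg$hours[1], cfg$participants)
  })
  streams <- lapply(seq_len(cfg$participants), function(i) {
    generate_stream(cfg, sprintf("SP%02d", i), hours[i],
                    (cfg$seed * 1000L + i) %% .Machine$integer.max)
  })
  labels <- unlist(lapply(streams, function(s) s$data$label))
  attr(streams, "manifest") <- if (any(labels != "NULL")) {
    imbalance_stats(labels, seconds_per = 1 / cfg$sample_rate_hz)
  }
  streams
}

#' Corruption model for ground-truth label streams
#'
#' Emulates the error modes of an imperfect window classifier directly on a
#' label stream: per-step misses (activity frames flipped to NULL),
#' spurious activity insertions in the NULL background (predicted events in
#' the wild tend to be small), and fragmentation holes punched inside true
#' events. Length is conserved; deterministic given the seed.
#'
#' @param gt a [prediction_stream()] (or label vector) of ground truth.
#' @param miss_rate per-step probability of flipping an activity frame to
#'   NULL.
#' @param insert_rate expected fraction of NULL steps converted to spurious
#'   activity (inserted events number about
#'   `insert_rate * n_null / insert_mean_len`).
#' @param insert_mean_len mean length (steps) of an inserted spurious run.
#' @param frag_rate per-event probability of punching a NULL hole inside a
#'   true event.
#' @param frag_hole_len hole length in steps (holes at least as long as the
#'   event delete it entirely).
#' @param seed RNG seed.
#' @return corrupted [prediction_stream()].
#' @export
corrupt_predictions <- function(gt, miss_rate = 0, insert_rate = 0,
                                insert_mean_len = 8, frag_rate = 0,
                                frag_hole_len = 4, seed = 1) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, insert_rate >= 0,
            insert_rate <= 1, frag_rate >= 0, frag_rate <= 1)
  stream <- if (inherits(gt, "prediction_stream")) gt
            else prediction_stream(gt)
  p <- stream$labels
  n <- length(p)
  if (n == 0L) return(stream)
  acts <- activity_classes()
  with_seed(seed, {
    # fragmentation holes inside true events
    if (frag_rate > 0) {
      for (cl in intersect(unique(p), acts)) {
        ev <- frames_to_events(p, cl)
        for (k in seq_len(nrow(ev))) {
          if (stats::runif(1) < frag_rate) {
            len <- ev$end[k] - ev$start[k]
            if (frag_hole_len >= len) {
              p[(ev$start[k] + 1):ev$end[k]] <- "NULL"
            } else {
              h0 <- ev$start[k] + sample.int(len - frag_hole_len + 1, 1)
              p[h0:(h0 + frag_hole_len - 1)] <- "NULL"
            }
          }
        }
      }
    }
    # per-step misses
    if (miss_rate > 0) {
      act_idx <- which(p %in% acts)
      flip <- act_idx[stats::runif(length(act_idx)) < miss_rate]
      p[flip] <- "NULL"
    }
    # spurious insertions in the NULL background
    if (insert_rate > 0) {
      i <- 1L
      start_prob <- insert_rate / insert_mean_len
      while (i <= n) {
        if (p[i] == "NULL" && stats::runif(1) < start_prob) {
          len <- stats::rgeom(1, 1 / insert_mean_len) + 1L
          j <- min(n, i + len - 1L)
          run <- i:j
          run <- run[p[run] == "NULL"]
          p[run] <- sample(acts, 1)
          i <- j + 1L
        } else i <- i + 1L
      }
    }
    prediction_stream(p, stream$stride_s, stream$start_s)
  })
}
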