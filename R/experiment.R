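#' Imbalance statistics of a label set
#'
#' Per-class imbalance ratio `IR_a = (n - |C_a|) / |C_a|`, where `n` counts
#' every instance including the NULL class and `|C_a|` the instances of
#' activity class `a`, and their average over the activity classes (the NULL
#' class contributes to `n` but is not one of the `k` averaged classes).
#'
#' @param labels character vector of per-sample or per-window labels.
#' @param seconds_per optional seconds represented by each label, to report
#'   per-class hours.
#' @return object of class `adl_imbalance`: list with `per_class`
#'   (data.frame of count, optional hours, IR) and `ir_avg`.
#' @export
imbalance_stats <- function(labels, seconds_per = NULL) {
  labels <- as.character(labels)
  counts <- table(labels)
  acts <- intersect(activity_classes(), names(counts))
  if (!length(acts)) stop("no activity class present")
  n <- sum(counts)
  per <- data.frame(class = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (!is.null(seconds_per)) per$hours <- per$count * seconds_per / 3600
  per$ir <- ifelse(per$class == "NULL", NA_real_,
                   (n - per$count) / per$count)
  structure(list(per_class = per,
                 ir_avg = mean(per$ir[per$class %in% acts]),
                 n = n, k = length(acts)),
            class = "adl_imbalance")
}

#' @export
print.adl_imbalance <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("average IR over %d activity classes: %.2f\n", x$k, x$ir_avg))
  invisible(x)
}

#' Reference class hours and imbalance ratios
#'
#' Published per-class data sizes (hours) and imbalance ratios from the
#' in-the-wild dual-wrist smartwatch ADL study that motivates this package:
#' 106.74 h of recording, of which 5.84 h are ADLs, with per-class imbalance
#' ratios between roughly 45 and 510. The printed per-class IRs were
#' computed from unrounded instance counts, so they cannot be recovered from
#' the rounded hours; both are carried as printed.
#'
#' @return data.frame with columns `class`, `hours`, `ir` (IR is `NA` for
#'   the NULL class).
#' @export
reference_class_stats <- function() {
  data.frame(
    class = c("BrushingTeeth", "CombingHair", "Drinking", "Eating", "NULL",
              "TakingMedication", "Walking", "WashingHands"),
    hours = c(0.24, 0.23, 0.21, 2.13, 100.90, 0.29, 2.32, 0.44),
    ir = c(500.72, 457.15, 509.85, 48.83, NA, 364.25, 44.78, 239.08),
    stringsAsFactors = FALSE)
}

#' Published recording totals
#'
#' Total and ADL recording hours as printed in the study summary (the
#' per-class hours of [reference_class_stats()] are rounded independently
#' and sum to slightly different values).
#' @return named numeric vector `c(total_hours, adl_hours)`.
#' @export
reference_recording_totals <- function() {
  c(total_hours = 106.74, adl_hours = 5.84)
}

#' Share of recording time spent on ADLs
#'
#' @param adl_hours,total_hours recording totals; defaults are the published
#'   values from [reference_recording_totals()].
#' @return percentage of recording time carrying an activity label.
#' @export
adl_share_pct <- function(adl_hours = reference_recording_totals()[["adl_hours"]],
                          total_hours = reference_recording_totals()[["total_hours"]]) {
  100 * adl_hours / total_hours
}

# Per-session per-class ADL seconds, for split balancing.
session_class_seconds <- function(streams) {
  t(vapply(streams, function(s) {
    sec <- table(factor(s$data$label, levels = activity_classes()))
    as.numeric(sec) / s$sample_rate_hz
  }, numeric(length(activity_classes()))))
}

#' Participant-stratified train/validation/evaluation split
#'
#' Assigns whole sessions (contiguous streams) to the three splits by a
#' greedy scheme that fills each split's per-class ADL-hour targets:
#' sessions are taken in decreasing order of total ADL time and each goes to
#' the split with the largest normalized remaining need. Every session stays
#' whole; with `by_participant = TRUE` (strict user independence, the
#' default) all sessions of a participant land in the same split.
#'
#' @param streams list of [sensor_stream()]s.
#' @param fractions target hour fractions, default `c(0.7, 0.2, 0.1)` for
#'   train/validation/evaluation.
#' @param seed RNG seed (used only to shuffle tied sessions).
#' @param by_participant keep all sessions of one participant together.
#' @return named character vector: split (`"train"`, `"validation"`,
#'   `"evaluation"`) per stream, in input order; achieved per-split ADL-hour
#'   fractions as attribute `achieved`.
#' @export
participant_split <- function(streams, fractions = c(0.7, 0.2, 0.1),
                              seed = 1, by_participant = TRUE) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-6)
  if (length(streams) < 3L) stop("fewer sessions than splits")
  splits <- c("train", "validation", "evaluation")
  mat <- session_class_seconds(streams)
  key <- if (by_participant) {
    vapply(streams, function(s) s$participant, "")
  } else {
    vapply(streams, function(s) s$session, "")
  }
  groups <- split(seq_along(streams), key)
  gmat <- t(vapply(groups, function(ix)
    colSums(mat[ix, , drop = FALSE]), numeric(ncol(mat))))
  gtot <- rowSums(gmat)
  ghrs <- vapply(groups, function(ix) sum(vapply(
    streams[ix], stream_duration_s, 0)), 0)
  ord <- with_seed(seed, order(gtot, sample.int(length(groups)),
                               decreasing = TRUE))
  tot_c <- colSums(gmat)
  tot_h <- sum(ghrs)
  cur_c <- matrix(0, 3, ncol(gmat))
  cur_h <- numeric(3)
  assign_g <- character(length(groups))
  for (g in ord) {
    need <- vapply(1:3, function(s) {
      class_need <- sum(pmax(fractions[s] * tot_c - cur_c[s, ], 0) /
                          pmax(tot_c, 1))
      hour_need <- max(fractions[s] * tot_h - cur_h[s], 0) / tot_h
      class_need + hour_need
    }, 0)
    s <- which.max(need)
    assign_g[g] <- splits[s]
    cur_c[s, ] <- cur_c[s, ] + gmat[g, ]
    cur_h[s] <- cur_h[s] + ghrs[g]
  }
  out <- character(length(streams))
  for (g in seq_along(groups)) out[groups[[g]]] <- assign_g[g]
  achieved <- vapply(splits, function(s) {
    sum(ghrs[assign_g == s]) / tot_h
  }, 0)
  structure(stats::setNames(out, vapply(streams, function(s) s$session, "")),
            achieved = achieved)
}

#' Grid of postprocessing configurations
#'
#' The full sweep evaluated on validation data: every context size in
#' `ws_s` crossed with every weighting function (the defaults give the
#' 24-size-by-5-function grid of 120 configurations).
#'
#' @param ws_s context sizes in seconds (default 10 s to 240 s by 10 s).
#' @param fns weighting function ids.
#' @return data.frame with columns `fn`, `ws_s`.
#' @export
postprocess_grid <- function(ws_s = seq(10, 240, by = 10),
                             fns = paste0("W", 1:5)) {
  expand.grid(fn = fns, ws_s = ws_s, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("fn", "ws_s")]
}

results_row <- function(trial, model, post, ws_s, sc) {
  data.frame(trial = trial, model = model, postprocess = post,
             ws_s = ws_s,
             P_macro = sc$window[["P_macro"]],
             R_macro = sc$window[["R_macro"]],
             F1_macro = sc$window[["F1_macro"]],
             P_event = sc$pooled[["P"]], R_event = sc$pooled[["R"]],
             F1_event = sc$pooled[["F1"]], stringsAsFactors = FALSE)
}

#' Train the preprocessing-by-model grid and sweep postprocessing
#'
#' Trains each (preprocessing, model-family) cell on the training features,
#' scores its raw prediction stream on validation, then — for the
#' `postprocess_top` cells with the highest pooled event-level F1 — sweeps
#' the postprocessing grid on the cached validation predictions (the
#' correction is prediction-level, so models are trained once). Naive Bayes
#' is skipped in the cost-sensitive trial.
#'
#' @param train_features,val_features `adl_features` for disjoint splits.
#' @param val_gt ground-truth [prediction_stream()] for the validation
#'   split (defaults to the validation window labels).
#' @param models model families to train.
#' @param preprocess preprocessing trials: subset of
#'   `c("none", "rus", "ros", "csl")`.
#' @param grid postprocessing grid from [postprocess_grid()].
#' @param postprocess_top number of best cells to sweep the grid on.
#' @param seed seed for resampling and model fits.
#' @return `adl_results`: a results data.frame (one row per trial-model and
#'   per swept postprocessing config) with the trained models and cached
#'   prediction streams in attributes `models` / `predictions`, and the best
#'   row (by pooled event F1, ties to smaller ws) in attribute `best`.
#' @export
run_grid <- function(train_features, val_features, val_gt = NULL,
                     models = c("xgboost", "random_forest"),
                     preprocess = c("none", "ros"),
                     grid = postprocess_grid(), postprocess_top = 1,
                     seed = 1) {
  if (is.null(val_gt)) {
    val_gt <- prediction_stream(as.character(val_features$label),
                                stride_s = attr(val_features, "stride_s")
                                %||% 0.25)
  }
  cells <- expand.grid(model = models, trial = preprocess,
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$model == "naive_bayes" & cells$trial == "csl"), ]
  rows <- list()
  fits <- list()
  preds <- list()
  for (i in seq_len(nrow(cells))) {
    trial <- cells$trial[i]
    fam <- cells$model[i]
    feats <- if (trial %in% c("rus", "ros")) {
      resample_features(train_features, trial, seed)
    } else train_features
    cw <- if (trial == "csl") {
      balanced_class_weights(as.character(feats$label))
    } else NULL
    cfg <- model_config(fam, class_weights = cw, seed = seed)
    fit <- train_model(feats, cfg)
    pr <- predict_stream(fit, val_features)
    key <- paste(trial, fam, sep = ":")
    fits[[key]] <- fit
    preds[[key]] <- pr
    rows[[key]] <- results_row(trial, fam, "-", NA_real_,
                               score_streams(val_gt, pr))
  }
  base <- do.call(rbind, rows)
  top <- base[order(-base$F1_event), ][seq_len(min(postprocess_top,
                                                   nrow(base))), ]
  post_rows <- list()
  for (r in seq_len(nrow(top))) {
    key <- paste(top$trial[r], top$model[r], sep = ":")
    pr <- preds[[key]]
    for (g in seq_len(nrow(grid))) {
      cp <- correct_stream(pr, fn = grid$fn[g], ws_s = grid$ws_s[g])
      post_rows[[paste(key, g)]] <-
        results_row(top$trial[r], top$model[r], grid$fn[g], grid$ws_s[g],
                    score_streams(val_gt, cp))
    }
  }
  res <- rbind(base, do.call(rbind, post_rows))
  rownames(res) <- NULL
  best <- res[order(-res$F1_event, res$ws_s), ][1, ]
  structure(res, models = fits, predictions = preds, best = best,
            class = c("adl_results", "data.frame"))
}

#' Final evaluation on the held-out split
#'
#' Scores a selected model on evaluation features with and without the
#' selected postprocessing configuration. Reports pooled and per-class event
#' metrics (every activity class is listed, including classes scored 0) and
#' the window-level confusion matrix.
#'
#' @param model a trained [train_model()] result.
#' @param eval_features held-out `adl_features` (untouched by selection).
#' @param eval_gt ground-truth stream (defaults to the window labels).
#' @param fn,ws_s selected postprocessing configuration.
#' @return list with `table` (two result rows), `per_class` (event metrics
#'   by class, with and without postprocessing), and `confusion`
#'   (ground-truth rows by predicted columns, raw predictions).
#' @export
final_evaluate <- function(model, eval_features, eval_gt = NULL,
                           fn = "W4", ws_s = 160) {
  if (is.null(eval_gt)) {
    eval_gt <- prediction_stream(as.character(eval_features$label),
                                 stride_s = attr(eval_features, "stride_s")
                                 %||% 0.25)
  }
  pr <- predict_stream(model, eval_features)
  cp <- correct_stream(pr, fn = fn, ws_s = ws_s)
  raw <- score_streams(eval_gt, pr)
  post <- score_streams(eval_gt, cp)
  vocab <- label_vocabulary()
  confusion <- table(factor(eval_gt$labels, levels = vocab),
                     factor(pr$labels, levels = vocab),
                     dnn = c("truth", "predicted"))
  per_class <- merge(raw$per_class[, c("class", "P", "R", "F1")],
                     post$per_class[, c("class", "P", "R", "F1")],
                     by = "class", suffixes = c("", "_post"))
  list(table = rbind(results_row("final", model$family, "-", NA_real_, raw),
                     results_row("final", model$family, fn, ws_s, post)),
       per_class = per_class, confusion = confusion,
       predictions = list(raw = pr, postprocessed = cp))
}
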