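# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder apportionment of `total` into shares proportional to w.
apportion <- function(w, total) {
  stopifnot(all(w > 0), total >= 0)
  quota <- total * w / sum(w)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, w, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Random undersampling of the majority (NULL) class
#'
#' Downsamples the majority class without replacement to exactly the total
#' count of all non-majority rows; minority rows are untouched. Row order of
#' the input is preserved in the output.
#'
#' @param features an `adl_features` data.frame (or any data.frame with a
#'   `label` column).
#' @param seed RNG seed; the selection is deterministic given the seed.
#' @param majority label of the majority class (default `"NULL"`).
#' @return data.frame of the same shape with the majority class reduced.
#' @export
random_undersample <- function(features, seed = 1, majority = "NULL") {
  lab <- as.character(features$label)
  is_maj <- lab == majority
  n_min <- sum(!is_maj)
  if (sum(is_maj) < n_min) {
    stop("majority class smaller than the non-majority total; ",
         "dataset is not majority-dominated")
  }
  keep_maj <- with_seed(seed, sort(sample(which(is_maj), n_min)))
  keep <- sort(c(which(!is_maj), keep_maj))
  features[keep, , drop = FALSE]
}

#' Ratio-preserving random oversampling of minority classes
#'
#' Duplicates minority-class rows (sampling with replacement) so that the
#' total minority count equals the majority count while pairwise ratios
#' between minority classes are preserved up to the one-unit rounding of
#' largest-remainder apportionment. The majority class is untouched. This
#' deliberately does not balance every class to the majority size: with
#' extreme imbalance ratios that would impose a near-uniform class prior.
#'
#' @inheritParams random_undersample
#' @return data.frame with duplicated minority rows appended.
#' @export
ratio_preserving_oversample <- function(features, seed = 1,
                                        majority = "NULL") {
  lab <- as.character(features$label)
  counts <- table(lab)
  if (!majority %in% names(counts)) stop("majority class absent")
  n_maj <- counts[[majority]]
  min_counts <- counts[names(counts) != majority]
  if (!length(min_counts)) stop("no minority class present")
  if (any(min_counts == 0)) stop("minority class with zero instances")
  targets <- apportion(as.numeric(min_counts), n_maj)
  names(targets) <- names(min_counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(min_counts), function(cl) {
      need <- targets[[cl]] - min_counts[[cl]]
      rows <- which(lab == cl)
      if (need > 0) sample(rows, need, replace = TRUE)
      else if (need < 0) -sample(rows, -need)  # degenerate: trim, warn below
      else integer(0)
    }))
  })
  drop <- -extra[extra < 0]
  add <- extra[extra > 0]
  if (length(drop)) {
    warning("minority total exceeds majority; trimming to preserve ratios")
  }
  keep <- setdiff(seq_len(nrow(features)), drop)
  features[c(keep, add), , drop = FALSE]
}

#' Balanced (inverse-frequency) class weights
#'
#' `weight_c = n_total / (n_classes * count_c)`: each class is weighted
#' inversely proportionally to its size, normalized so equal counts give
#' weight 1 everywhere.
#'
#' @param counts named vector or `table` of per-class instance counts
#'   (all > 0), or a `label` vector to tabulate.
#' @return named numeric vector of weights.
#' @export
balanced_class_weights <- function(counts) {
  if (is.character(counts) || is.factor(counts)) counts <- table(counts)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (any(counts <= 0)) stop("zero-count class in weight computation")
  sum(counts) / (length(counts) * counts)
}

#' Apply a named resampling method to a training feature matrix
#'
#' @param features training `adl_features`.
#' @param method `"none"`, `"rus"` (random undersampling) or `"ros"`
#'   (ratio-preserving oversampling).
#' @param seed RNG seed for the resampler.
#' @export
resample_features <- function(features, method = c("none", "rus", "ros"),
                              seed = 1) {
  switch(match.arg(method),
         none = features,
         rus = random_undersample(features, seed),
         ros = ratio_preserving_oversample(features, seed))
}
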