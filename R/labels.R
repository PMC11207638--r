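#' Label vocabulary
#'
#' Seven activities of daily living (ADLs) plus the `NULL` background class.
#' The `NULL` class collects every sample that does not belong to an activity
#' of interest; in unscripted recordings it is the overwhelming majority.
#'
#' @return `activity_classes()` returns the 7 ADL labels;
#'   `label_vocabulary()` returns the 8-label closed vocabulary including
#'   `"NULL"`.
#' @export
activity_classes <- function() {
  c("BrushingTeeth", "CombingHair", "Drinking", "Eating",
    "TakingMedication", "Walking", "WashingHands")
}

#' @rdname activity_classes
#' @export
label_vocabulary <- function() c(activity_classes(), "NULL")

#' Default relabeling map
#'
#' Maps raw annotation-app labels onto the closed vocabulary. Canonical labels
#' map to themselves; the app's spaced button texts are normalized;
#' `"Clapping"` and `"Nothing"` map to `"NULL"`; brushing performed with an
#' electric toothbrush (raw label `"BrushingTeeth:electric"`) maps to `"NULL"`
#' because it lacks the arm movement of manual brushing. Raw labels of the
#' form `"Other:<text>"` are handled by rule in [apply_relabel()]: any text
#' mentioning stairs becomes `"Walking"`, every other `"Other:*"` becomes
#' `"NULL"`.
#'
#' @return Named character vector: names are raw labels, values canonical.
#' @export
default_relabel_map <- function() {
  canon <- label_vocabulary()
  map <- stats::setNames(canon, canon)
  c(map,
    "Brushing Teeth"        = "BrushingTeeth",
    "Combing Hair"          = "CombingHair",
    "Taking Meds"           = "TakingMedication",
    "Washing Hands"         = "WashingHands",
    "Nothing"               = "NULL",
    "Clapping"              = "NULL",
    "BrushingTeeth:electric" = "NULL")
}

#' Apply a relabeling map to raw labels
#'
#' @param labels character vector of raw labels.
#' @param map named character vector (raw -> canonical); default
#'   [default_relabel_map()].
#' @return character vector of canonical labels (closed vocabulary).
#' @export
apply_relabel <- function(labels, map = default_relabel_map()) {
  labels <- as.character(labels)
  out <- unname(map[labels])
  miss <- which(is.na(out))
  if (length(miss)) {
    raw <- labels[miss]
    other <- grepl("^Other:", raw)
    out[miss[other & grepl("stairs", tolower(raw))]] <- "Walking"
    out[miss[other & !grepl("stairs", tolower(raw))]] <- "NULL"
    unknown <- unique(raw[!other])
    if (length(unknown)) {
      stop("unknown label(s) with no map entry: ",
           paste(unknown, collapse = ", "))
    }
  }
  bad <- setdiff(unique(out), label_vocabulary())
  if (length(bad)) {
    stop("relabel map produces labels outside the vocabulary: ",
         paste(bad, collapse = ", "))
  }
  out
}
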