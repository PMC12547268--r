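#' Confusion counts
#'
#' True positives, false positives and false negatives from which precision,
#' recall and F1 derive. For the movement counter a TP is a predicted
#' crossing matched (in time and direction) to a reference crossing; for the
#' litter counter per-observation counts are compared, so a surplus of
#' predicted hens contributes FPs and a deficit FNs.
#'
#' @param TP,FP,FN nonnegative counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0, FP = 0, FN = 0) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- precision_recall_f1(x)
  cat(sprintf("TP=%g FP=%g FN=%g  precision=%.2f recall=%.2f F1=%.2f\n",
              x$TP, x$FP, x$FN, m$precision, m$recall, m$f1))
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$TP + e2$TP, e1$FP + e2$FP, e1$FN + e2$FN)
}

#' Match predicted crossing events against reference events
#'
#' Greedy one-to-one chronological matching: predicted events are taken in
#' time order and each is matched to the earliest still-unmatched reference
#' event with the same direction within `tolerance` seconds. Matched pairs
#' are TPs, unmatched predictions FPs, unmatched references FNs. For 1-D
#' tolerance windows this greedy scheme attains the maximum matching.
#'
#' @param predicted,reference event data frames with `time_s` and
#'   `direction`, time-sorted.
#' @param tolerance matching tolerance in seconds (default 0.5, i.e. 2
#'   frames at 4 frames/s).
#' @return a `confusion_counts`.
#' @export
match_events <- function(predicted, reference, tolerance = 0.5) {
  p <- predicted[order(predicted$time_s), , drop = FALSE]
  r <- reference[order(reference$time_s), , drop = FALSE]
  used <- rep(FALSE, nrow(r))
  tp <- 0L
  for (i in seq_len(nrow(p))) {
    cand <- which(!used & r$direction == p$direction[i] &
                    abs(r$time_s - p$time_s[i]) <= tolerance)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  confusion_counts(TP = tp, FP = nrow(p) - tp, FN = nrow(r) - tp)
}

#' Confusion counts from paired count observations
#'
#' Per observation with `n` predicted and `m` reference hens: TP = min(n, m),
#' FP = max(n - m, 0), FN = max(m - n, 0); accumulated by summation over
#' observations.
#'
#' @param predicted_count,reference_count nonnegative integer vectors of
#'   equal length (one entry per observation).
#' @return a `confusion_counts`.
#' @export
count_confusion <- function(predicted_count, reference_count) {
  stopifnot(length(predicted_count) == length(reference_count),
            all(predicted_count >= 0), all(reference_count >= 0))
  confusion_counts(TP = sum(pmin(predicted_count, reference_count)),
                   FP = sum(pmax(predicted_count - reference_count, 0)),
                   FN = sum(pmax(reference_count - predicted_count, 0)))
}

#' Precision, recall and F1 score
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall). An undefined metric
#' (zero denominator) is reported as `NA` with a warning.
#'
#' @param c a `confusion_counts`, or precision/recall supplied directly via
#'   `precision` and `recall`.
#' @param precision,recall alternative direct inputs (both required if `c`
#'   is missing), for recomputing F1 from reported precision/recall pairs.
#' @return list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(c = NULL, precision = NULL, recall = NULL) {
  if (!is.null(c)) {
    precision <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
    recall <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
    if (is.na(precision)) warning("precision undefined (TP + FP = 0)")
    if (is.na(recall)) warning("recall undefined (TP + FN = 0)")
  } else if (is.null(precision) || is.null(recall)) {
    stop("supply confusion counts or both precision and recall")
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Write an evaluation report (CSV + JSON summary)
#'
#' @param rows data frame with columns `video_id, measure, TP, FP, FN`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return the report data frame with appended metric columns (metrics at
#'   full precision in the CSV; the JSON summary rounds to 2 decimals).
#' @export
evaluation_report <- function(rows, csv_path = NULL, json_path = NULL) {
  met <- t(vapply(seq_len(nrow(rows)), function(i) {
    m <- precision_recall_f1(confusion_counts(rows$TP[i], rows$FP[i],
                                              rows$FN[i]))
    c(m$precision, m$recall, m$f1)
  }, numeric(3)))
  rows$precision <- met[, 1]; rows$recall <- met[, 2]; rows$f1 <- met[, 3]
  if (!is.null(csv_path))
    utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(lapply(seq_len(nrow(rows)), function(i)
      list(video_id = rows$video_id[i], measure = rows$measure[i],
           precision = round(rows$precision[i], 2),
           recall = round(rows$recall[i], 2), f1 = round(rows$f1[i], 2))),
      json_path, auto_unbox = TRUE)
  rows
}
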