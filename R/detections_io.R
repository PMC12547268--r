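#' Bounding-box hen detections
#'
#' One row per detected hen: frame index, box corners in pixels, confidence
#' score, and the derived box center used for zone assignment.
#'
#' @param frame_index integer frame index (0-based or 1-based, caller's
#'   convention; kept as given).
#' @param x1,y1,x2,y2 box corners in pixels, `x1 < x2`, `y1 < y2`.
#' @param score confidence in `[0, 1]`.
#' @return a `data.frame` of class `detections` with derived `cx`, `cy`.
#' @export
detections <- function(frame_index, x1, y1, x2, y2, score = 1) {
  df <- data.frame(frame_index = as.integer(frame_index),
                   x1 = as.numeric(x1), y1 = as.numeric(y1),
                   x2 = as.numeric(x2), y2 = as.numeric(y2),
                   score = as.numeric(score))
  validate_detections(df)
}

validate_detections <- function(df, frame_width = NULL, frame_height = NULL) {
  need <- c("frame_index", "x1", "y1", "x2", "y2", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("detections missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- which(df$x1 >= df$x2 | df$y1 >= df$y2)
    if (length(bad)) stop("invalid box (x1>=x2 or y1>=y2) at row ", bad[1])
    bad <- which(df$score < 0 | df$score > 1)
    if (length(bad)) stop("score outside [0,1] at row ", bad[1])
    if (!is.null(frame_width)) {
      bad <- which(df$x1 < 0 | df$y1 < 0 |
                   df$x2 > frame_width | df$y2 > frame_height)
      if (length(bad)) stop("box outside frame bounds at row ", bad[1])
    }
  }
  df$cx <- (df$x1 + df$x2) / 2
  df$cy <- (df$y1 + df$y2) / 2
  class(df) <- c("detections", "data.frame")
  df
}

#' Read externally produced detections (CSV)
#'
#' Lets users substitute any external detector (for example a trained
#' neural-network hen detector) for the built-in reference detector. Columns:
#' `frame_index,x1,y1,x2,y2,score`.
#'
#' @param path CSV path.
#' @return validated `detections` with derived centers.
#' @export
ingest_detections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(validate_detections(df),
           error = function(e) stop("in ", path, ": ", conditionMessage(e)))
}

#' @rdname ingest_detections
#' @param dets a `detections` data frame.
#' @export
write_detections <- function(dets, path) {
  out <- as.data.frame(dets)[, c("frame_index", "x1", "y1", "x2", "y2", "score")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
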