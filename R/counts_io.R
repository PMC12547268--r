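#' Per-interval count records
#'
#' The tabular unit shared by every stage: a nonnegative integer count
#' (vertical movements per interval, or hens per litter zone per interval)
#' keyed by experimental group, week, day type and clock time.
#'
#' @param group_id character or coercible group identifier.
#' @param week integer week number (>= 1).
#' @param day_type one of `"visual"`, `"frustrative"`, `"auditory"`,
#'   `"control"`.
#' @param clock_time seconds since midnight at the start of the interval.
#' @param interval_s interval length in seconds (60 per-minute, 1 per-second).
#' @param measure `"vertical_movement"` or `"litter_zone_count"`.
#' @param zone_label optional zone label (litter counts), else `NA`.
#' @param value nonnegative integer count.
#' @return a `data.frame` of class `count_records`, sorted by key.
#' @export
count_records <- function(group_id, week, day_type, clock_time, interval_s,
                          measure, zone_label = NA_character_, value) {
  df <- data.frame(group_id = as.character(group_id),
                   week = as.integer(week),
                   day_type = as.character(day_type),
                   clock_time = as.numeric(clock_time),
                   interval_s = as.numeric(interval_s),
                   measure = as.character(measure),
                   zone_label = as.character(zone_label),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_count_records(df)
}

DAY_TYPES <- c("visual", "frustrative", "auditory", "control")
MEASURES <- c("vertical_movement", "litter_zone_count")

validate_count_records <- function(df) {
  need <- c("group_id", "week", "day_type", "clock_time", "interval_s",
            "measure", "zone_label", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("count records missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$value < 0)) stop("negative counts in count records")
    if (any(df$week < 1)) stop("week must be >= 1")
    if (any(df$interval_s <= 0)) stop("interval_s must be > 0")
    bad <- setdiff(unique(df$day_type), DAY_TYPES)
    if (length(bad)) stop("unknown day_type: ", paste(bad, collapse = ", "))
    key <- with(df, paste(group_id, week, day_type, clock_time, measure,
                          zone_label, sep = "\r"))
    if (anyDuplicated(key)) stop("duplicate (group, week, day_type, time, ",
                                 "measure, zone) keys in count records")
    df <- df[order(df$group_id, df$week, df$day_type, df$clock_time,
                   df$measure, df$zone_label), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("count_records", "data.frame")
  df
}

#' Convert seconds since midnight to "HH:MM:SS" and back
#' @param s seconds since midnight.
#' @return character clock time.
#' @export
seconds_to_clock <- function(s) {
  s <- round(as.numeric(s))
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' @rdname seconds_to_clock
#' @param clock character "HH:MM:SS" (or "HH:MM").
#' @export
clock_to_seconds <- function(clock) {
  vapply(strsplit(as.character(clock), ":"), function(p) {
    p <- as.numeric(p)
    if (length(p) == 2) p <- c(p, 0)
    if (length(p) != 3 || any(is.na(p))) stop("bad clock time: ", clock[1])
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

#' Read / write per-interval count tables
#'
#' CSV dialect: UTF-8, comma-separated, mandatory header
#' `group_id,week,day_type,clock_time,interval_s,measure,zone_label,value`,
#' with ISO-8601 `HH:MM:SS` clock times. The round-trip is lossless and
#' records are returned sorted by (group, week, day type, clock time).
#'
#' @param path CSV file path.
#' @return `read_counts`: validated `count_records`; `write_counts`: `path`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(group_id = "character",
                                       zone_label = "character"))
  if (nrow(df) == 0) {
    df$zone_label <- as.character(df$zone_label)
    return(validate_count_records(df))
  }
  df$clock_time <- clock_to_seconds(df$clock_time)
  df$zone_label[df$zone_label == ""] <- NA_character_
  validate_count_records(df)
}

#' @rdname read_counts
#' @param records a `count_records` data frame.
#' @export
write_counts <- function(records, path) {
  records <- validate_count_records(as.data.frame(records))
  out <- records
  out$clock_time <- seconds_to_clock(out$clock_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
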