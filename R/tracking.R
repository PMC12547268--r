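#' Track set for motion-blob association
#'
#' Minimal container for centroid tracks: each track is an ordered set of
#' (frame, x, y, zone) observations with strictly increasing frame indices.
#' Directionality of a zone crossing is read off a track, not off raw masks.
#'
#' @return an empty `track_set`.
#' @export
track_set <- function() {
  structure(list(tracks = list(), next_id = 1L), class = "track_set")
}

new_track <- function(id, frame, x, y, zone) {
  list(track_id = id,
       obs = data.frame(frame = frame, x = x, y = y, zone = zone),
       last_frame = frame, closed = FALSE)
}

#' Greedy nearest-neighbour association of blobs to open tracks
#'
#' Candidate (track, blob) pairs are taken in ascending distance order
#' (ties broken by lower track id, then blob order); each track and blob is
#' used at most once, and pairs farther than `max_link_distance` are never
#' linked. Unmatched blobs open new tracks. Open tracks not updated for more
#' than `max_gap` frames are closed. Deterministic given input order.
#'
#' @param ts a `track_set`.
#' @param blobs blob data frame from [extract_blobs()] (single frame).
#' @param frame integer frame index of `blobs`.
#' @param max_link_distance maximum centroid displacement in pixels.
#' @param max_gap maximum unmatched frames before a track is closed.
#' @return the updated `track_set`.
#' @export
associate <- function(ts, blobs, frame, max_link_distance = 100, max_gap = 2) {
  open_idx <- which(vapply(ts$tracks, function(t) !t$closed, logical(1)))
  nb <- nrow(blobs)
  matched_track <- integer(0)
  matched_blob <- integer(0)
  if (length(open_idx) && nb) {
    cand <- expand.grid(ti = open_idx, bi = seq_len(nb))
    cand$d <- vapply(seq_len(nrow(cand)), function(i) {
      tr <- ts$tracks[[cand$ti[i]]]
      last <- tr$obs[nrow(tr$obs), ]
      sqrt((last$x - blobs$x[cand$bi[i]])^2 + (last$y - blobs$y[cand$bi[i]])^2)
    }, numeric(1))
    cand <- cand[cand$d <= max_link_distance, , drop = FALSE]
    cand$tid <- vapply(cand$ti, function(i) ts$tracks[[i]]$track_id, integer(1))
    cand <- cand[order(cand$d, cand$tid, cand$bi), , drop = FALSE]
    used_t <- logical(length(ts$tracks)); used_b <- logical(nb)
    for (i in seq_len(nrow(cand))) {
      ti <- cand$ti[i]; bi <- cand$bi[i]
      if (used_t[ti] || used_b[bi]) next
      used_t[ti] <- TRUE; used_b[bi] <- TRUE
      matched_track <- c(matched_track, ti)
      matched_blob <- c(matched_blob, bi)
    }
  }
  for (j in seq_along(matched_track)) {
    ti <- matched_track[j]; bi <- matched_blob[j]
    tr <- ts$tracks[[ti]]
    tr$obs <- rbind(tr$obs, data.frame(frame = frame, x = blobs$x[bi],
                                       y = blobs$y[bi],
                                       zone = blobs$zone[bi]))
    tr$last_frame <- frame
    ts$tracks[[ti]] <- tr
  }
  if (nb) {
    for (bi in setdiff(seq_len(nb), matched_blob)) {
      ts$tracks[[length(ts$tracks) + 1L]] <-
        new_track(ts$next_id, frame, blobs$x[bi], blobs$y[bi], blobs$zone[bi])
      ts$next_id <- ts$next_id + 1L
    }
  }
  for (i in seq_along(ts$tracks)) {
    tr <- ts$tracks[[i]]
    if (!tr$closed && frame - tr$last_frame > max_gap) {
      tr$closed <- TRUE
      ts$tracks[[i]] <- tr
    }
  }
  ts
}

#' Directed crossing events from zone-labelled tracks
#'
#' One event per consecutive observation pair whose zones differ and are both
#' non-missing. The event time is the later frame's timestamp; direction is
#' `"up"` iff the target zone index is smaller (toward the upmost tier under
#' the top-to-bottom convention). Observations with missing zone (exclusion
#' region, e.g. the stairs) break the pair, so no event is counted across
#' them.
#'
#' @param ts a `track_set` whose observations carry zone indices.
#' @param frame_rate frames per second (frame i has time (i-1)/rate).
#' @return data frame `time_s, from_zone, to_zone, direction, track_id`,
#'   sorted by time.
#' @export
detect_crossings <- function(ts, frame_rate = 4) {
  out <- list()
  for (tr in ts$tracks) {
    ob <- tr$obs
    if (nrow(ob) < 2) next
    for (i in 2:nrow(ob)) {
      z0 <- ob$zone[i - 1]; z1 <- ob$zone[i]
      if (is.na(z0) || is.na(z1) || z0 == z1) next
      out[[length(out) + 1L]] <-
        data.frame(time_s = (ob$frame[i] - 1) / frame_rate,
                   from_zone = z0, to_zone = z1,
                   direction = if (z1 < z0) "up" else "down",
                   track_id = tr$track_id)
    }
  }
  if (!length(out))
    return(data.frame(time_s = numeric(0), from_zone = integer(0),
                      to_zone = integer(0), direction = character(0),
                      track_id = integer(0)))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$time_s, ev$track_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Aggregate crossing events to per-minute counts
#'
#' Counts events per wall-clock minute over the observation window; minutes
#' with no events emit value 0. Optionally split by direction.
#'
#' @param events crossing-event data frame (`time_s`, `direction`).
#' @param duration_s observation length in seconds (defines the minute bins;
#'   default: last event time rounded up to a full minute).
#' @param group_id,week,day_type,clock_anchor record metadata; `clock_anchor`
#'   is the clock time (s since midnight) of `time_s = 0`.
#' @param by_direction if `TRUE`, one record per direction per minute with
#'   `zone_label` set to the direction.
#' @return a `count_records` data frame (measure `"vertical_movement"`).
#' @export
aggregate_per_minute <- function(events, duration_s = NULL, group_id = "G1",
                                 week = 1, day_type = "control",
                                 clock_anchor = 0, by_direction = FALSE) {
  if (is.null(duration_s))
    duration_s <- if (nrow(events)) 60 * ceiling(max(events$time_s) / 60) else 60
  n_min <- max(1L, ceiling(duration_s / 60))
  minute_of <- function(t) pmin(n_min - 1L, floor(t / 60))
  mk <- function(vals, lab) {
    data.frame(group_id = group_id, week = week, day_type = day_type,
               clock_time = clock_anchor + 60 * (seq_len(n_min) - 1),
               interval_s = 60, measure = "vertical_movement",
               zone_label = lab, value = as.numeric(vals),
               stringsAsFactors = FALSE)
  }
  if (by_direction) {
    df <- do.call(rbind, lapply(c("up", "down"), function(d) {
      tt <- events$time_s[events$direction == d]
      mk(tabulate(minute_of(tt) + 1L, nbins = n_min), d)
    }))
  } else {
    df <- mk(tabulate(minute_of(events$time_s) + 1L, nbins = n_min),
             NA_character_)
  }
  validate_count_records(df)
}

#' Count vertical movements in a frame series
#'
#' The full counting pipeline: (optional subsampling to the processing rate,
#' default 4 frames/s) -> Gaussian blur -> consecutive-frame absolute
#' difference -> thresholded motion mask -> 8-connected blobs with exclusion
#' filtering -> greedy nearest-neighbour tracks -> zone-change events ->
#' per-minute counts.
#'
#' @param fs a [frame_series()].
#' @param zonemap the 4-zone side-view [zone_map()].
#' @param config list of parameters: `blur_kernel` (5), `blur_sigma` (NULL),
#'   `diff_threshold` (25), `min_area` (pi * (radius/2)^2 for the configured
#'   hen radius, default radius 10), `max_link_distance` (70), `max_gap`
#'   (2), `frame_rate` (4), `polarity` (`"bright"` for hens brighter than
#'   background, `"dark"` otherwise): the tracker follows appearance blobs
#'   of the signed frame difference, which isolates the bird's current
#'   position from the double image that absolute differencing produces.
#' @param metadata list passed to [aggregate_per_minute()] (`group_id`,
#'   `week`, `day_type`, `clock_anchor`).
#' @return list with `events`, `minute_counts`, and the final `tracks`.
#' @export
count_movements <- function(fs, zonemap, config = list(), metadata = list()) {
  cfg <- utils::modifyList(list(blur_kernel = 5, blur_sigma = NULL,
                                diff_threshold = 25, agent_radius = 10,
                                min_area = NULL, max_link_distance = 70,
                                max_gap = 2, frame_rate = 4,
                                polarity = "bright"), config)
  if (is.null(cfg$min_area)) cfg$min_area <- pi * (cfg$agent_radius / 2)^2
  if (fs$frame_rate > cfg$frame_rate) fs <- subsample_frames(fs, cfg$frame_rate)
  mode <- if (identical(cfg$polarity, "dark")) "disappear" else "appear"
  ts <- track_set()
  prev <- preprocess(fs$frames[[1]], cfg$blur_kernel, cfg$blur_sigma)
  for (f in seq_along(fs$frames)[-1]) {
    cur <- preprocess(fs$frames[[f]], cfg$blur_kernel, cfg$blur_sigma)
    mask <- frame_difference(prev, cur, cfg$diff_threshold, mode = mode)
    blobs <- extract_blobs(mask, cfg$min_area, zonemap)
    ts <- associate(ts, blobs, f, cfg$max_link_distance, cfg$max_gap)
    prev <- cur
  }
  events <- detect_crossings(ts, fs$frame_rate)
  md <- utils::modifyList(list(group_id = "G1", week = 1,
                               day_type = "control", clock_anchor = 0),
                          metadata)
  counts <- aggregate_per_minute(events,
                                 duration_s = length(fs$frames) / fs$frame_rate,
                                 group_id = md$group_id, week = md$week,
                                 day_type = md$day_type,
                                 clock_anchor = md$clock_anchor)
  list(events = events, minute_counts = counts, tracks = ts)
}
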