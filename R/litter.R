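#' Litter grid: 2-zone litter map plus physical scale
#'
#' The litter camera views 4 m^2 of litter split into a system-side and a
#' wall-side zone. Densities in hens/m^2 are derived as count / litter_area.
#'
#' @param zonemap a 2-zone [zone_map()] (see [litter_zone_map()]).
#' @param litter_area viewed litter area in m^2 (default 4).
#' @param px_per_m optional pixel scale.
#' @return an object of class `litter_grid`.
#' @export
litter_grid <- function(zonemap = NULL, litter_area = 4, px_per_m = NULL) {
  if (is.null(zonemap)) zonemap <- litter_zone_map(640, 480)
  if (n_zones(zonemap) != 2) stop("litter grid needs exactly 2 zones")
  if (litter_area <= 0) stop("litter_area must be > 0")
  structure(list(zonemap = zonemap, litter_area = litter_area,
                 px_per_m = px_per_m),
            class = "litter_grid")
}

#' Background-subtraction reference hen detector
#'
#' A deliberately simple stand-in for a trained neural detector, adequate for
#' synthetic scenes: `|frame - background|` is thresholded and 8-connected
#' components with area in `[min_area, max_area]` are reported as bounding
#' boxes with score 1.0.
#'
#' @param frame,background same-size greyscale matrices.
#' @param threshold grey-level threshold.
#' @param min_area,max_area component area bounds in pixels^2.
#' @param frame_index frame index recorded in the output.
#' @return a `detections` data frame.
#' @export
reference_detect <- function(frame, background, threshold = 25,
                             min_area = 40, max_area = 5000,
                             frame_index = 1L) {
  if (!identical(dim(frame), dim(background)))
    stop("frame/background size mismatch")
  mask <- abs(frame - background) > threshold
  blobs <- extract_blobs(mask, min_area, zonemap = NULL, max_area = max_area)
  if (!nrow(blobs))
    return(validate_detections(data.frame(frame_index = integer(0),
                                          x1 = numeric(0), y1 = numeric(0),
                                          x2 = numeric(0), y2 = numeric(0),
                                          score = numeric(0))))
  validate_detections(data.frame(frame_index = as.integer(frame_index),
                                 x1 = blobs$x1, y1 = blobs$y1,
                                 x2 = blobs$x2, y2 = blobs$y2, score = 1))
}

#' Per-zone hen counts for one frame
#'
#' Each detection is assigned by its box center via [assign_zone()];
#' detections whose center lies outside both litter zones are dropped (and
#' counted in the `dropped` attribute).
#'
#' @param dets `detections` from one frame.
#' @param grid a [litter_grid()].
#' @return named integer vector of per-zone counts (attribute `dropped`).
#' @export
zone_counts <- function(dets, grid) {
  labs <- zone_labels(grid$zonemap)
  if (!nrow(dets)) {
    out <- stats::setNames(rep(0L, length(labs)), labs)
    attr(out, "dropped") <- 0L
    return(out)
  }
  z <- assign_zones(cbind(dets$cx, dets$cy), grid$zonemap)
  out <- stats::setNames(
    vapply(seq_along(labs), function(i) sum(z == i, na.rm = TRUE), integer(1)),
    labs)
  attr(out, "dropped") <- sum(is.na(z))
  out
}

#' Hen density over the viewed litter area
#' @param total_count total hens counted on the litter.
#' @param grid a [litter_grid()].
#' @return hens/m^2.
#' @export
litter_density <- function(total_count, grid) {
  if (grid$litter_area <= 0) stop("zero litter area")
  total_count / grid$litter_area
}

#' Spatial occupancy heatmap of detection centers
#'
#' 2-D histogram of detection centers over a time window, normalized to sum
#' to 1 when nonempty.
#'
#' @param dets `detections` accumulated over a window.
#' @param bins integer `c(nx, ny)` bin counts.
#' @param frame_width,frame_height extent of the binning grid in pixels.
#' @return `ny` x `nx` matrix of bin masses (rows = image rows, top first).
#' @export
occupancy_heatmap <- function(dets, bins = c(8, 6), frame_width = 640,
                              frame_height = 480) {
  nx <- bins[1]; ny <- bins[2]
  stopifnot(nx >= 1, ny >= 1)
  hm <- matrix(0, ny, nx)
  if (nrow(dets)) {
    bx <- pmin(nx, pmax(1, ceiling(dets$cx / frame_width * nx)))
    by <- pmin(ny, pmax(1, ceiling(dets$cy / frame_height * ny)))
    for (i in seq_along(bx)) hm[by[i], bx[i]] <- hm[by[i], bx[i]] + 1
    hm <- hm / sum(hm)
  }
  hm
}

#' Aggregate per-frame zone counts into an occupancy series
#'
#' Per-interval mean count per zone (unrounded by default), emitted as
#' `count_records` at the requested interval (1 s and/or 60 s granularity).
#'
#' @param frame_counts data frame `frame, zone_label, count` (one row per
#'   frame per zone).
#' @param frame_rate frames per second.
#' @param interval_s aggregation interval in seconds.
#' @param group_id,week,day_type,clock_anchor record metadata.
#' @param round_fun function applied to interval means (default identity).
#' @return a `count_records` data frame (measure `"litter_zone_count"`).
#' @export
aggregate_series <- function(frame_counts, frame_rate = 4, interval_s = 60,
                             group_id = "G1", week = 1, day_type = "control",
                             clock_anchor = 0, round_fun = identity) {
  stopifnot(nrow(frame_counts) > 0)
  t_s <- (frame_counts$frame - 1) / frame_rate
  bin <- floor(t_s / interval_s)
  n_bins <- max(bin) + 1
  rows <- list()
  for (lab in unique(frame_counts$zone_label)) {
    sel <- frame_counts$zone_label == lab
    m <- tapply(frame_counts$count[sel], factor(bin[sel], levels = 0:(n_bins - 1)),
                mean)
    m[is.na(m)] <- 0
    rows[[lab]] <- data.frame(group_id = group_id, week = week,
                              day_type = day_type,
                              clock_time = clock_anchor + interval_s * (0:(n_bins - 1)),
                              interval_s = interval_s,
                              measure = "litter_zone_count",
                              zone_label = lab,
                              value = as.numeric(round_fun(m)),
                              stringsAsFactors = FALSE)
  }
  validate_count_records(do.call(rbind, rows))
}

#' Count hens per litter zone over a frame series
#'
#' Runs [reference_detect()] on every frame against a background image and
#' accumulates per-frame zone counts plus the pooled detections.
#'
#' @param fs a [frame_series()].
#' @param background background matrix (no hens).
#' @param grid a [litter_grid()].
#' @param config list: `threshold` (25), `min_area` (40), `max_area` (5000).
#' @return list with `frame_counts` (frame, zone_label, count), `detections`
#'   (pooled), and `dropped` (total centers outside both zones).
#' @export
count_litter <- function(fs, background, grid, config = list()) {
  cfg <- utils::modifyList(list(threshold = 25, min_area = 40,
                                max_area = 5000), config)
  labs <- zone_labels(grid$zonemap)
  rows <- list(); all_dets <- list(); dropped <- 0L
  for (f in seq_along(fs$frames)) {
    d <- reference_detect(fs$frames[[f]], background, cfg$threshold,
                          cfg$min_area, cfg$max_area, frame_index = f)
    zc <- zone_counts(d, grid)
    dropped <- dropped + attr(zc, "dropped")
    rows[[f]] <- data.frame(frame = f, zone_label = labs,
                            count = as.numeric(zc))
    all_dets[[f]] <- d
  }
  dets <- do.call(rbind, all_dets)
  class(dets) <- c("detections", "data.frame")
  list(frame_counts = do.call(rbind, rows), detections = dets,
       dropped = dropped)
}
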