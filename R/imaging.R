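#' Greyscale frame series
#'
#' Frames are integer matrices in `[0, 255]`, indexed `[y, x]` (row = image
#' row, origin top-left), held in a list together with the frame rate. The
#' default processing rate is 4 frames/s; higher-rate input is subsampled to
#' this rate before analysis.
#'
#' @param frames list of equal-size numeric matrices.
#' @param frame_rate frames per second.
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_rate = 4) {
  stopifnot(length(frames) >= 1, frame_rate > 0)
  d <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), d)) stop("frames differ in size")
  structure(list(frames = frames, frame_rate = frame_rate,
                 width = d[2], height = d[1]),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames, %d x %d px, %.3g fps\n",
              length(x$frames), x$width, x$height, x$frame_rate))
  invisible(x)
}

#' Subsample a frame series to a target rate
#' @param fs a [frame_series()].
#' @param target_rate desired frames/s; must not exceed the input rate.
#' @return a [frame_series()] at (approximately) the target rate.
#' @export
subsample_frames <- function(fs, target_rate = 4) {
  if (target_rate > fs$frame_rate)
    stop("cannot upsample: input is ", fs$frame_rate, " fps")
  step <- fs$frame_rate / target_rate
  idx <- unique(pmin(length(fs$frames), round(seq(1, length(fs$frames), by = step))))
  frame_series(fs$frames[idx], target_rate)
}

# ---- plain-text PGM (P2) I/O ----------------------------------------------

# clip to [0, 255] preserving matrix shape (pmax/pmin would drop dim)
clip_grey <- function(mat) {
  mat <- round(mat)
  mat[mat < 0] <- 0
  mat[mat > 255] <- 255
  mat
}

write_pgm <- function(mat, path) {
  mat <- clip_grey(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), "255"), con)
  apply_rows <- apply(mat, 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not a plain PGM (P2) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write / read a frame series as a PGM sequence plus JSON manifest
#'
#' Frames go to `frame_000001.pgm`, ... (plain-text PGM, readable by common
#' imaging tools); `manifest.json` records frame rate, size and count.
#'
#' @param fs a [frame_series()].
#' @param dir output directory (created if needed).
#' @return the directory (write) or a [frame_series()] (read).
#' @export
write_frames <- function(fs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fs$frames))
    write_pgm(fs$frames[[i]], file.path(dir, sprintf("frame_%06d.pgm", i)))
  jsonlite::write_json(list(frame_rate = fs$frame_rate, width = fs$width,
                            height = fs$height, n_frames = length(fs$frames),
                            format = "pgm"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.pgm$",
                           full.names = TRUE))
  if (length(files) != man$n_frames)
    stop("manifest lists ", man$n_frames, " frames, found ", length(files))
  frame_series(lapply(files, read_pgm), man$frame_rate)
}

# ---- preprocessing ---------------------------------------------------------

gaussian_kernel_1d <- function(ksize = 5, sigma = NULL) {
  stopifnot(ksize %% 2 == 1, ksize >= 1)
  # sigma default follows the common CV convention for a given kernel size
  if (is.null(sigma)) sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  x <- seq(-(ksize - 1) / 2, (ksize - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicate border padding
convolve_separable <- function(mat, k) {
  r <- (length(k) - 1) / 2
  h <- nrow(mat); w <- ncol(mat)
  # rows direction (vertical): pad rows by replication
  padded <- mat[c(rep(1, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * padded[(i - 1) + seq_len(h), , drop = FALSE]
  padded <- out[, c(rep(1, r), seq_len(w), rep(w, r)), drop = FALSE]
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) out2 <- out2 + k[i] * padded[, (i - 1) + seq_len(w), drop = FALSE]
  out2
}

#' Smooth a greyscale frame with a Gaussian blur
#'
#' The denoising step applied to every frame before differencing. Kernel size
#' and sigma are configurable; sigma defaults to the usual size-derived value.
#'
#' @param frame numeric matrix (single-channel frame).
#' @param ksize odd kernel size (default 5, i.e. 5x5).
#' @param sigma Gaussian sigma; `NULL` for the size-derived default.
#' @return smoothed numeric matrix of the same size.
#' @export
preprocess <- function(frame, ksize = 5, sigma = NULL) {
  if (length(frame) == 0) stop("empty frame")
  frame <- as.matrix(frame)
  convolve_separable(frame, gaussian_kernel_1d(ksize, sigma))
}

#' Binary motion mask from two consecutive frames
#'
#' In the default `"abs"` mode a pixel is flagged as motion iff
#' `|cur - prev| > threshold` (absolute frame difference, default threshold
#' 25 grey levels). Frame differencing of a moving body leaves a double
#' image — one blob where it was, one where it now is — so the counting
#' pipeline uses the signed modes to isolate the current position:
#' `"appear"` flags `cur - prev > threshold` (where a bright body arrived)
#' and `"disappear"` flags `prev - cur > threshold`.
#'
#' @param prev,cur same-size numeric matrices.
#' @param threshold grey-level threshold (strict inequality).
#' @param mode `"abs"` (default), `"appear"` or `"disappear"`.
#' @return logical matrix, `TRUE` where motion exceeds the threshold.
#' @export
frame_difference <- function(prev, cur, threshold = 25,
                             mode = c("abs", "appear", "disappear")) {
  if (!identical(dim(prev), dim(cur))) stop("frame size mismatch")
  switch(match.arg(mode),
         abs = abs(cur - prev) > threshold,
         appear = (cur - prev) > threshold,
         disappear = (prev - cur) > threshold)
}

# ---- connected components --------------------------------------------------

# label 8-connected TRUE pixels; returns integer matrix (0 = background)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  current <- 0L
  # neighbour offsets in (row, col)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    stack <- start
    lab[start] <- current
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr <- ((p - 1L) %% h) + 1L
      pc <- ((p - 1L) %/% h) + 1L
      nr <- pr + dr; nc <- pc + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx)) {
        lab[nidx] <- current
        stack <- c(stack, nidx)
      }
    }
  }
  lab
}

#' Extract motion blobs from a binary mask
#'
#' 8-connected components of area >= `min_area`, reported with their
#' area-weighted centroid in pixel coordinates. When a `zonemap` is supplied,
#' blobs whose centroid falls inside an exclusion polygon are dropped (motion
#' on the stairs is never counted) and each blob carries its zone index.
#'
#' @param mask logical matrix from [frame_difference()].
#' @param min_area minimum component area in pixels^2.
#' @param zonemap optional [zone_map()] for exclusion filtering and zone
#'   labelling.
#' @param max_area optional maximum component area (used by the litter
#'   reference detector); `Inf` to disable.
#' @return `data.frame` with columns `x`, `y`, `area` (and `zone`,
#'   `x1,y1,x2,y2` bounding box).
#' @export
extract_blobs <- function(mask, min_area = 20, zonemap = NULL,
                          max_area = Inf) {
  lab <- label_components(mask)
  out <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                    x1 = numeric(0), y1 = numeric(0),
                    x2 = numeric(0), y2 = numeric(0),
                    zone = integer(0))
  if (!any(lab > 0L)) return(out)
  idx <- which(lab > 0L)
  h <- nrow(mask)
  comp <- lab[idx]
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  area <- tapply(rep(1, length(idx)), comp, sum)
  cx <- tapply(cols, comp, mean)
  cy <- tapply(rows, comp, mean)
  bx1 <- tapply(cols, comp, min); bx2 <- tapply(cols, comp, max)
  by1 <- tapply(rows, comp, min); by2 <- tapply(rows, comp, max)
  keep <- area >= min_area & area <= max_area
  out <- data.frame(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
                    area = as.numeric(area[keep]),
                    x1 = as.numeric(bx1[keep]), y1 = as.numeric(by1[keep]),
                    x2 = as.numeric(bx2[keep]), y2 = as.numeric(by2[keep]),
                    zone = rep(NA_integer_, sum(keep)))
  if (!is.null(zonemap) && nrow(out)) {
    out$zone <- assign_zones(cbind(out$x, out$y), zonemap)
    excluded <- vapply(seq_len(nrow(out)), function(i) {
      for (e in zonemap$exclusion_polygons)
        if (point_in_polygon(out$x[i], out$y[i], e) != "outside") return(TRUE)
      FALSE
    }, logical(1))
    out <- out[!excluded, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
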