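# Independent oracles used by the property tests. Each reimplements the
# checked primitive with a different algorithm than the package.

# winding-number point-in-polygon (package uses even-odd crossing count)
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  wn <- 0
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    j <- if (i == n) 1 else i + 1
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if (y1 <= y) {
      if (y2 > y && (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1) > 0)
        wn <- wn + 1
    } else {
      if (y2 <= y && (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}

# direct (non-separable) 2-D convolution with replicate padding
oracle_convolve <- function(mat, ksize, sigma) {
  k1 <- flockmotion:::gaussian_kernel_1d(ksize, sigma)
  K <- outer(k1, k1)
  r <- (ksize - 1) / 2
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      acc <- acc + K[di + r + 1, dj + r + 1] * mat[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# 8-connected labelling by iterative minimum-label propagation
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# canonical partition signature of a labelling (algorithm-independent)
partition_signature <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  sig <- lapply(ids, function(i) sort(which(lab == i)))
  sig[order(vapply(sig, `[`, integer(1), 1))]
}

# exhaustive maximum one-to-one event matching (for lists of <= 6 events)
oracle_max_matching <- function(predicted, reference, tolerance) {
  np <- nrow(predicted); nr <- nrow(reference)
  compat <- outer(seq_len(np), seq_len(nr), Vectorize(function(i, j)
    predicted$direction[i] == reference$direction[j] &&
      abs(predicted$time_s[i] - reference$time_s[j]) <= tolerance))
  best <- 0L
  assign_next <- function(i, used, count) {
    if (i > np) { best <<- max(best, count); return(invisible()) }
    assign_next(i + 1L, used, count)            # leave i unmatched
    for (j in seq_len(nr)) {
      if (!used[j] && compat[i, j]) {
        used[j] <- TRUE
        assign_next(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, max(nr, 1)), 0L)
  best
}

# random convex polygon (points on a circle, guaranteed simple)
random_convex_polygon <- function(n, cx, cy, r) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# small labelled count series with exact per-week activity means
make_labeled_records <- function(week_values, activity = "A",
                                 n_minutes = 3, groups = "G1") {
  rows <- list()
  for (w in seq_along(week_values)) for (g in groups) {
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = g, week = w, day_type = "control",
      clock_time = 3600 + 60 * (seq_len(n_minutes) - 1), interval_s = 60,
      measure = "vertical_movement", zone_label = NA_character_,
      value = week_values[w], activity = activity,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# default 4-band aviary map used across tests
test_zone_map <- function(width = 640, height = 480)
  stacked_zone_map(width, height, 4, stairs = c(500, 240, 560, 480))
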