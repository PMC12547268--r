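test_that("preprocess blur: constant, impulse mass, convolution oracle", {
  const <- matrix(77, 20, 20)
  expect_equal(preprocess(const), const)

  imp <- matrix(0, 15, 15); imp[8, 8] <- 100
  sm <- preprocess(imp, ksize = 5)
  expect_equal(sum(sm), 100, tolerance = 1e-10)      # mass preserved
  expect_equal(which.max(sm), which.max(imp))        # kernel centred
  expect_true(all(sm[8 + (-2:2), 8 + (-2:2)] > 0))
  expect_equal(sum(sm[8 + (-2:2), 8 + (-2:2)]), 100, tolerance = 1e-10)

  set.seed(10)
  img <- matrix(stats::runif(18 * 13, 0, 255), 13, 18)
  expect_equal(preprocess(img, ksize = 5),
               oracle_convolve(img, 5, NULL), tolerance = 1e-10)
  expect_equal(preprocess(img, ksize = 3, sigma = 1.2),
               oracle_convolve(img, 3, 1.2), tolerance = 1e-10)
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "empty")
})

test_that("frame_difference: identity, moved disk, pixel-loop oracle, modes", {
  a <- matrix(50, 12, 12)
  expect_false(any(frame_difference(a, a)))
  expect_error(frame_difference(a, matrix(0, 5, 5)), "mismatch")

  # a bright disk moved by its diameter: mask covers old+new footprints only
  mk_disk <- function(cx, cy, r, h = 40, w = 40) {
    m <- matrix(0, h, w)
    for (y in 1:h) for (x in 1:w)
      if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y, x] <- 200
    m
  }
  prev <- mk_disk(12, 20, 5); cur <- mk_disk(22, 20, 5)
  mask <- frame_difference(prev, cur, 25)
  expect_identical(mask, (prev > 0) != (cur > 0))
  expect_identical(frame_difference(prev, cur, 25, mode = "appear"),
                   cur > prev + 25)
  expect_identical(frame_difference(prev, cur, 25, mode = "disappear"),
                   prev > cur + 25)

  set.seed(11)
  p <- matrix(sample(0:255, 400, TRUE), 20, 20)
  q <- matrix(sample(0:255, 400, TRUE), 20, 20)
  loop <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20) loop[i, j] <- abs(q[i, j] - p[i, j]) > 25
  expect_identical(frame_difference(p, q, 25), loop)

  # monotonicity: raising the threshold never adds motion pixels
  counts <- vapply(c(0, 10, 25, 60, 120), function(th)
    sum(frame_difference(p, q, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("extract_blobs: construction cases and flood-fill oracle", {
  expect_equal(nrow(extract_blobs(matrix(FALSE, 10, 10), 5)), 0L)

  m <- matrix(FALSE, 40, 40)
  m[5:14, 5:14] <- TRUE    # 100 px square
  m[25:34, 25:34] <- TRUE
  b <- extract_blobs(m, min_area = 50)
  expect_equal(nrow(b), 2L)
  expect_equal(sort(b$x), c(9.5, 29.5))
  expect_equal(sort(b$y), c(9.5, 29.5))
  expect_equal(b$area, c(100, 100))
  expect_equal(nrow(extract_blobs(m, min_area = 101)), 0L)

  # labelling partition matches the independent propagation oracle
  set.seed(12)
  for (rep in 1:5) {
    mm <- matrix(stats::runif(30 * 30) < 0.3, 30, 30)
    expect_identical(partition_signature(flockmotion:::label_components(mm)),
                     partition_signature(oracle_label(mm)))
  }

  # centroid inside an exclusion region drops the blob
  zm2 <- zone_map(40, 40,
                  list(list(label = "a", polygon = rbind(c(0, 0), c(40, 0),
                                                         c(40, 40), c(0, 40)))),
                  list(rbind(c(20, 20), c(40, 20), c(40, 40), c(20, 40))))
  mex <- matrix(FALSE, 40, 40)
  mex[28:33, 28:33] <- TRUE   # centroid (30.5, 30.5) inside exclusion
  mex[3:8, 3:8] <- TRUE
  bex <- extract_blobs(mex, min_area = 10, zonemap = zm2)
  expect_equal(nrow(bex), 1L)
  expect_lt(bex$x, 10)
})

test_that("associate: link, new track, exhaustive 2x2 oracle", {
  ts <- track_set()
  ts <- associate(ts, data.frame(x = 10, y = 10, zone = 1L), frame = 1,
                  max_link_distance = 20)
  ts <- associate(ts, data.frame(x = 12, y = 10, zone = 1L), frame = 2,
                  max_link_distance = 20)
  expect_equal(length(ts$tracks), 1L)
  expect_equal(nrow(ts$tracks[[1]]$obs), 2L)

  # too far: opens a new track
  ts <- associate(ts, data.frame(x = 90, y = 90, zone = 2L), frame = 3,
                  max_link_distance = 20)
  expect_equal(length(ts$tracks), 2L)

  # track closure after max_gap unmatched frames
  ts <- associate(ts, data.frame(x = numeric(0), y = numeric(0),
                                 zone = integer(0)), frame = 7, max_gap = 2)
  expect_true(all(vapply(ts$tracks, `[[`, logical(1), "closed")))

  # 2 tracks x 2 blobs: greedy equals the exhaustive minimum-total-distance
  # assignment when distances are unambiguous
  ts2 <- track_set()
  ts2 <- associate(ts2, data.frame(x = c(0, 50), y = c(0, 0),
                                   zone = c(1L, 1L)), frame = 1)
  blobs <- data.frame(x = c(8, 44), y = c(0, 0), zone = c(1L, 1L))
  # exhaustive: pairing (t1-b1, t2-b2) costs 8+6=14; crossed costs 44+42=86
  ts2 <- associate(ts2, blobs, frame = 2, max_link_distance = 60)
  expect_equal(length(ts2$tracks), 2L)
  expect_equal(ts2$tracks[[1]]$obs$x, c(0, 8))
  expect_equal(ts2$tracks[[2]]$obs$x, c(50, 44))
})

test_that("detect_crossings: direction, stairs break, event time", {
  mk_track <- function(zones, frames = seq_along(zones)) {
    ts <- track_set()
    for (i in seq_along(zones))
      ts <- associate(ts, data.frame(x = 10, y = 10 * i, zone = zones[i]),
                      frame = frames[i], max_link_distance = 1e6)
    ts
  }
  ev <- detect_crossings(mk_track(c(4L, 4L, 3L, 3L)), frame_rate = 4)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$from_zone, 4L)
  expect_equal(ev$to_zone, 3L)
  expect_equal(ev$direction, "up")
  expect_equal(ev$time_s, (3 - 1) / 4)

  # an excluded (stairs) observation breaks the pair: no event across it
  ev2 <- detect_crossings(mk_track(c(2L, NA, 3L)), frame_rate = 4)
  expect_equal(nrow(ev2), 0L)

  ev3 <- detect_crossings(mk_track(c(1L, 2L, 2L, 1L)), frame_rate = 4)
  expect_equal(ev3$direction, c("down", "up"))
})

test_that("aggregate_per_minute: binning, zero-fill, conservation", {
  ev <- data.frame(time_s = c(10, 70, 130), direction = c("up", "down", "up"))
  cr <- aggregate_per_minute(ev, duration_s = 180)
  expect_equal(cr$value, c(1, 1, 1))

  empty <- data.frame(time_s = numeric(0), direction = character(0))
  expect_equal(aggregate_per_minute(empty, duration_s = 300)$value,
               rep(0, 5))

  # direction split conserves the total per minute
  set.seed(13)
  ev2 <- data.frame(time_s = sort(stats::runif(40, 0, 600)),
                    direction = sample(c("up", "down"), 40, TRUE))
  tot <- aggregate_per_minute(ev2, duration_s = 600)
  byd <- aggregate_per_minute(ev2, duration_s = 600, by_direction = TRUE)
  up <- byd$value[byd$zone_label == "up"]
  down <- byd$value[byd$zone_label == "down"]
  expect_equal(up + down, tot$value)
  expect_equal(sum(tot$value), nrow(ev2))
})

test_that("end-to-end: noiseless synthetic events recovered exactly", {
  zm <- stacked_zone_map(320, 240, 4)
  sc <- video_scenario(zonemap = zm, n_agents = 4, agent_radius = 8,
                       duration = 30, agent_spacing = 75,
                       crossing_rates = do.call(rbind, lapply(1:3, function(i)
                         data.frame(from = c(i, i + 1L), to = c(i + 1L, i),
                                    rate = 2))),
                       seed = 13)
  truth <- simulate_crossing_schedule(sc)
  expect_gt(nrow(truth$events), 0)
  fs <- render_video(sc, truth)
  res <- count_movements(fs, zm, list(agent_radius = 8,
                                      max_link_distance = 40))
  ref <- transform(truth$events,
                   direction = ifelse(to_zone < from_zone, "up", "down"))
  cc <- match_events(res$events, ref, tolerance = 0.5)
  expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 0)
  expect_equal(cc$TP, nrow(truth$events))
  # endpoint zones agree event-by-event (both sorted by time)
  expect_equal(res$events$from_zone, truth$events$from_zone)
  expect_equal(res$events$to_zone, truth$events$to_zone)
  # minute totals conserve the schedule
  expect_equal(sum(res$minute_counts$value), nrow(truth$events))

  # idempotence: identical frames and config give byte-identical CSV output
  res2 <- count_movements(fs, zm, list(agent_radius = 8,
                                       max_link_distance = 40))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_counts(res$minute_counts, f1)
  write_counts(res2$minute_counts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("frame series subsampling honours the 4 fps processing rate", {
  frames <- lapply(1:24, function(i) matrix(i, 4, 4))
  fs8 <- frame_series(frames, frame_rate = 8)
  fs4 <- subsample_frames(fs8, 4)
  expect_equal(length(fs4$frames), 12L)
  expect_equal(fs4$frame_rate, 4)
  expect_error(subsample_frames(fs4, 8), "upsample")

  # PGM round trip
  dir <- withr::local_tempdir()
  write_frames(fs4, dir)
  back <- read_frames(dir)
  expect_equal(back$frames, fs4$frames)
  expect_equal(back$frame_rate, 4)
})
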