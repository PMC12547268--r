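test_that("default schedules place the stress categories at the protocol clock times", {
  vis <- build_schedule("visual")
  pc1 <- vis[vis$name == "Predator cue 1", ]
  expect_equal(seconds_to_clock(pc1$start_clock), "15:30:00")
  expect_equal(seconds_to_clock(pc1$end_clock), "15:33:00")
  pc2 <- vis[vis$name == "Predator cue 2", ]
  expect_equal(seconds_to_clock(pc2$end_clock), "15:36:00")
  expect_equal(sum(vis$duration_min), 120)

  fru <- build_schedule("frustrative")
  f1 <- fru[fru$name == "Frustration 1", ]
  expect_equal(seconds_to_clock(f1$start_clock), "10:00:00")
  expect_equal(seconds_to_clock(f1$end_clock), "10:15:00")

  aud <- build_schedule("auditory")
  th <- aud[aud$name == "Thunder sound", ]
  expect_equal(seconds_to_clock(th$start_clock), "15:30:00")
  expect_equal(th$duration_min, 1)

  # categories are contiguous: each starts where the previous ends
  for (s in list(vis, fru, aud))
    expect_equal(s$start_clock[-1], s$end_clock[-nrow(s)])

  expect_error(build_schedule("visual", config = list(
    anchor = "14:30:00",
    categories = data.frame(name = c("a", "b"), duration_min = c(5, 0)))),
    "> 0")
})

test_that("minute labelling respects category boundaries and partitions", {
  sched <- build_schedule("visual")
  rec <- count_records(group_id = "G1", week = 1, day_type = "visual",
                       clock_time = clock_to_seconds("14:30:00") +
                         60 * (0:119),
                       interval_s = 60, measure = "vertical_movement",
                       value = 1)
  lab <- label_minutes(rec, sched)
  expect_equal(lab$activity[lab$clock_time == clock_to_seconds("15:31:00")],
               "Predator cue 1")
  # boundary minute belongs to the category that starts at it
  expect_equal(lab$activity[lab$clock_time == clock_to_seconds("15:33:00")],
               "Predator cue 2")
  expect_equal(lab$activity[lab$clock_time == clock_to_seconds("14:30:00")],
               "Feeding 1")
  # partition: labelled minutes per category equal category durations
  tab <- table(lab$activity)
  expect_equal(as.integer(tab[sched$name]), sched$duration_min)

  # out-of-window records are flagged
  rec2 <- count_records(group_id = "G1", week = 1, day_type = "visual",
                        clock_time = clock_to_seconds("08:00:00"),
                        interval_s = 60, measure = "vertical_movement",
                        value = 1)
  expect_warning(lab2 <- label_minutes(rec2, sched), "unscheduled")
  expect_equal(lab2$activity, "unscheduled")
})

test_that("QCD reproduces reference table cells and is scale-free", {
  expect_equal(round(qcd(18.4, 24.7), 1), 14.6)   # feeding sound, visual day
  expect_equal(round(qcd(6.5, 12.6), 1), 31.9)    # predator cue 1
  expect_equal(round(qcd(28.7, 36.1), 1), 11.4)   # feeding sound, auditory day
  expect_equal(round(qcd(29.9, 39.7), 1), 14.1)   # frustration 1, litter
  expect_equal(qcd(5, 5), 0)
  expect_warning(expect_true(is.na(qcd(0, 0))), "undefined")
  set.seed(17)
  for (i in 1:20) {
    q <- sort(stats::runif(2, 1, 50))
    s <- stats::runif(1, 0.1, 10)
    expect_equal(qcd(s * q[1], s * q[2]), qcd(q[1], q[2]))
  }
})

test_that("weekly descriptives follow the groups-then-weeks aggregation", {
  # two groups whose minute values average to known per-week summaries
  weeks <- c(10, 12, 14, 16, 20)
  recs <- do.call(rbind, lapply(seq_along(weeks), function(w)
    do.call(rbind, lapply(c("G1", "G2"), function(g)
      data.frame(group_id = g, week = w, day_type = "control",
                 clock_time = 3600 + 60 * (0:2), interval_s = 60,
                 measure = "vertical_movement", zone_label = NA_character_,
                 # G1 = weeks value - 1, G2 = + 1 so the group mean is exact
                 value = weeks[w] + ifelse(g == "G1", -1, 1),
                 activity = "A", stringsAsFactors = FALSE)))))
  d <- weekly_descriptives(recs)
  qs <- stats::quantile(weeks, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(d$median, qs[2])
  expect_equal(d$Q1, qs[1])
  expect_equal(d$Q3, qs[3])
  expect_equal(d$IQR, qs[3] - qs[1])
  expect_equal(d$QCD, 100 * (qs[3] - qs[1]) / (qs[3] + qs[1]))
  expect_equal(d$weekly_min, 10)
  expect_equal(d$weekly_max, 20)
  expect_true(d$Q1 <= d$median && d$median <= d$Q3)

  # no-dispersion case
  d0 <- weekly_descriptives(make_labeled_records(rep(7, 4)))
  expect_equal(d0$IQR, 0)
  expect_equal(d0$QCD, 0)
})

test_that("Friedman: closed forms, stats::friedman.test oracle, exact p", {
  # perfect concordance, 3 blocks x 3 treatments
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  ft <- friedman_block_test(m)
  expect_equal(ft$chi2, 6)
  expect_equal(ft$W, 1)
  expect_equal(ft$df, 2)

  # complete ties
  ft0 <- friedman_block_test(matrix(5, 4, 3))
  expect_equal(ft0$chi2, 0)
  expect_equal(ft0$W, 0)

  # random matrices agree with the base-R implementation (ties included)
  set.seed(18)
  for (i in 1:10) {
    mm <- matrix(sample(1:5, 24, TRUE), 6, 4)
    ft1 <- friedman_block_test(mm)
    ft2 <- stats::friedman.test(mm)
    expect_equal(ft1$chi2, unname(ft2$statistic))
    expect_equal(ft1$p, ft2$p.value)
    expect_gte(ft1$W, 0); expect_lte(ft1$W, 1)
  }

  # chi2 invariant under within-block monotone transformation
  mm <- matrix(stats::runif(12, 1, 9), 4, 3)
  expect_equal(friedman_block_test(exp(mm))$chi2,
               friedman_block_test(mm)$chi2)

  # exact p on a 4x3 equals the full within-block permutation null applied
  # to the base-R statistic (independent oracle enumeration)
  m4 <- matrix(c(3, 1, 2, 2, 1, 3, 3, 2, 1, 1, 2, 3), 4, 3, byrow = TRUE)
  fte <- friedman_block_test(m4, p_method = "exact")
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  obs <- unname(stats::friedman.test(m4)$statistic)
  idx <- expand.grid(1:6, 1:6, 1:6, 1:6)
  null_stats <- apply(idx, 1, function(ii) {
    mp <- m4
    for (b in 1:4) mp[b, ] <- m4[b, perms[ii[b], ]]
    unname(stats::friedman.test(mp)$statistic)
  })
  expect_equal(fte$p, mean(null_stats >= obs - 1e-12))

  expect_error(friedman_block_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman_block_test(matrix(1, 1, 3)), ">= 2 blocks")
})

test_that("post hoc pairs: exact null, BH adjustment, Monte-Carlo accord", {
  # identical columns: all raw p = 1
  m <- matrix(rep(c(4, 7, 7, 9), 3), 4, 3)
  ph <- posthoc_pairs(m)
  expect_true(all(ph$raw_p == 1))
  expect_true(all(ph$adjusted_p >= ph$raw_p))

  # BH on (0.01, 0.02, 0.03): step-up gives (0.03, 0.03, 0.03)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # Monte-Carlo branch agrees with enumeration within 3 MC standard errors
  set.seed(19)
  m5 <- matrix(stats::runif(15, 0, 10), 5, 3)
  exact <- posthoc_pairs(m5, exact_max_blocks = 10)
  mc <- posthoc_pairs(m5, exact_max_blocks = 0, n_mc = 4000, seed = 3)
  for (i in seq_len(nrow(exact))) {
    se <- sqrt(exact$raw_p[i] * (1 - exact$raw_p[i]) / 4000)
    expect_lt(abs(mc$raw_p[i] - exact$raw_p[i]), 3 * se + 1e-3)
  }

  # a clearly separated pair gets a small adjusted p
  msep <- cbind(1:8, 1:8 + 10, 1:8 + 0.5)
  ph2 <- posthoc_pairs(msep)
  expect_lt(ph2$adjusted_p[1], 0.05)
})

test_that("friedman_matrix assembles weeks x activities summaries", {
  recs <- rbind(make_labeled_records(c(5, 6, 7), activity = "A"),
                make_labeled_records(c(9, 9, 9), activity = "B"))
  mat <- friedman_matrix(recs)
  expect_equal(dim(mat), c(3L, 2L))
  expect_equal(unname(mat[, "A"]), c(5, 6, 7))
  expect_equal(unname(mat[, "B"]), c(9, 9, 9))
})
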