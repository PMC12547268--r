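visual_short_params <- function(seed, week_sd = 0.23)
  count_sim_params(c(before = 15.6, during = 7.5, after = 11.4),
                   c(before = 5, during = 6, after = 5),
                   week_sd = week_sd, nb_dispersion = 10,
                   n_weeks = 10, n_groups = 4,
                   anchor_clock = clock_to_seconds("15:25:00"), seed = seed)

test_that("window specs encode the stressor phase windows", {
  # visual short: before 15:25-15:30, during 15:30-15:36, after 15:36-15:41
  rec <- simulate_count_series(visual_short_params(1))
  lab <- select_windows(rec, window_spec("visual", "short"),
                        onset_clock = clock_to_seconds("15:30:00"))
  rng <- function(ph) range(lab$clock_time[lab$phase == ph])
  expect_equal(seconds_to_clock(rng("before")), c("15:25:00", "15:29:00"))
  expect_equal(seconds_to_clock(rng("during")), c("15:30:00", "15:35:00"))
  expect_equal(seconds_to_clock(rng("after")), c("15:36:00", "15:40:00"))
  # group and week keys preserved, everything else dropped
  expect_equal(sort(unique(lab$group_id)), paste0("G", 1:4))
  expect_equal(sort(unique(lab$week)), 1:10)
  expect_equal(nrow(lab), nrow(rec))

  # auditory short: during is the single thunder minute
  aud <- window_spec("auditory", "short")
  expect_equal(aud$windows$during, c(0, 1))
  expect_equal(aud$windows$after, c(1, 5))

  # frustrative long, late anchor: during = last 30 min of the 60-min delay
  fru <- window_spec("frustrative", "long", "late")
  expect_equal(fru$windows$during, c(30, 30))
  expect_equal(fru$windows$before, c(-30, 30))
  expect_equal(fru$windows$after, c(60, 30))
  fre <- window_spec("frustrative", "short", "early")
  expect_equal(fre$windows$during, c(0, 5))

  # incomplete coverage errors and names missing minutes
  expect_error(select_windows(rec[rec$clock_time >
                                    clock_to_seconds("15:27:00"), ],
                              window_spec("visual", "short"),
                              onset_clock = clock_to_seconds("15:30:00")),
               "missing minutes.*15:25")
})

test_that("degenerate and fixed-effects fits behave as contracted", {
  # constant counts, no week effect: every phase mean equals the constant
  d <- data.frame(value = 7, phase = rep(c("before", "during", "after"),
                                         each = 20), week = 1)
  fit <- fit_nb_glmm(d, week_effect = FALSE)
  expect_equal(unname(fit$phase_means), rep(7, 3), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[-1]), c(0, 0), tolerance = 1e-8)

  # non-integer counts rejected
  expect_error(fit_nb_glmm(data.frame(value = 1.5, phase = "before",
                                      week = 1)), "nonnegative integers")
  expect_error(fit_nb_glmm(data.frame(value = c(1, 2),
                                      phase = c("before", "before"),
                                      week = 1)), ">= 2 phases")
})

test_that("week_sd = 0 route matches the independent NB regression oracle", {
  set.seed(20)
  for (k in c(3, 12)) {
    d <- data.frame(value = stats::rnbinom(360, size = k,
                                           mu = rep(c(15.6, 7.5, 11.4),
                                                    each = 120)),
                    phase = factor(rep(c("before", "during", "after"),
                                       each = 120),
                                   levels = c("before", "during", "after")),
                    week = rep(1:10, 36))
    mine <- fit_nb_glmm(d, week_effect = FALSE)
    oracle <- MASS::glm.nb(value ~ phase, data = d)
    expect_equal(unname(mine$coefficients), unname(stats::coef(oracle)),
                 tolerance = 1e-4)
    expect_equal(mine$dispersion, oracle$theta, tolerance = 1e-3)
    expect_equal(mine$log_likelihood, as.numeric(stats::logLik(oracle)),
                 tolerance = 1e-6)
  }
})

test_that("adding the week random effect never hurts the likelihood, and
           the NB2 fit approaches Poisson as dispersion grows", {
  s <- simulate_count_series(visual_short_params(31))
  glmm <- fit_nb_glmm(s)
  glm0 <- fit_nb_glmm(s, week_effect = FALSE)
  expect_gte(glmm$log_likelihood, glm0$log_likelihood - 1e-4)

  # Poisson-simulated data: NB2 ML means equal Poisson-regression means
  set.seed(22)
  dp <- data.frame(value = stats::rpois(300, rep(c(9, 14, 11), each = 100)),
                   phase = factor(rep(c("before", "during", "after"),
                                      each = 100),
                                  levels = c("before", "during", "after")),
                   week = 1)
  nb <- fit_nb_glmm(dp, week_effect = FALSE)
  po <- stats::glm(value ~ phase, family = stats::poisson(), data = dp)
  expect_equal(unname(nb$coefficients), unname(stats::coef(po)),
               tolerance = 1e-4)
  expect_gt(nb$dispersion, 100)   # dispersion heads to the Poisson limit
})

test_that("estimates are invariant to week relabelling", {
  s <- simulate_count_series(visual_short_params(33))
  f1 <- fit_nb_glmm(s)
  s2 <- s
  s2$week <- 100 + (s2$week * 7) %% 23   # arbitrary injective relabelling
  f2 <- fit_nb_glmm(s2)
  # identical up to optimiser tolerance (data row order changes)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-3)
  expect_equal(f1$week_sd, f2$week_sd, tolerance = 1e-2)
  expect_equal(f1$phase_means, f2$phase_means, tolerance = 1e-3)
})

test_that("parameter recovery on the simulated stress design", {
  mu <- c(before = 15.6, during = 7.5, after = 11.4)
  reps <- 100
  est <- matrix(NA_real_, reps, 3, dimnames = list(NULL, names(mu)))
  covered <- matrix(NA, reps, 3)
  for (r in seq_len(reps)) {
    s <- simulate_count_series(visual_short_params(2000 + r))
    fit <- fit_nb_glmm(s)
    est[r, ] <- fit$phase_means[names(mu)]
    ci <- phase_confint(fit, 0.95)
    covered[r, ] <- mu >= ci[names(mu), "lower"] & mu <= ci[names(mu), "upper"]
  }
  # 95% Wald-type intervals cover the truth in >= 90% of replicates
  expect_gte(mean(covered), 0.90)
  # during-phase estimates unbiased within Monte-Carlo error
  mc_se <- stats::sd(est[, "during"]) / sqrt(reps)
  expect_lt(abs(mean(est[, "during"]) - mu["during"]), 4 * mc_se)
  # reference short-term effect size: before - during rounds to 8
  expect_equal(round(mean(est[, "before"] - est[, "during"])), 8)
})

test_that("phase report mirrors the reference table layout", {
  s <- simulate_count_series(visual_short_params(40))
  fit <- fit_nb_glmm(s)
  rep_ <- phase_report(fit, durations_min = c(before = 5, during = 6,
                                              after = 5))
  expect_equal(rep_$phase, c("before", "during", "after"))
  expect_equal(rep_$duration_min, c(5, 6, 5))
  expect_true(is.na(rep_$p_vs_before[1]))
  expect_true(all(rep_$p_vs_before[-1] < 0.05))   # strong simulated contrasts
  expect_true(is.finite(attr(rep_, "week_sd_pred")))

  # CSV round trip preserves the table
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep_, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$mean, rep_$mean)
  expect_equal(back$phase, rep_$phase)

  # zero-contrast fit reports equal means and p-values present
  d0 <- data.frame(value = rep(c(5, 6, 7, 6, 5, 6), 30),
                   phase = rep(c("before", "during", "after"), 60),
                   week = rep(1:10, 18))
  f0 <- fit_nb_glmm(d0)
  r0 <- phase_report(f0)
  expect_equal(r0$mean[1], r0$mean[2], tolerance = 0.2)
  expect_true(all(!is.na(r0$p_vs_before[-1])))
})
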