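#' Default pipeline configuration
#'
#' One configuration object drives every stage; the JSON file mirrors this
#' structure section by section (`simulate`, `vertical_movement`, `litter`,
#' `schedule`, `stress`). The default synthetic day emulates a visual-stress
#' observation day: per-minute counts for the nine activity categories with
#' week-to-week log-normal variation, plus a small noiseless aviary scene
#' and litter scene for the vision stages.
#'
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      video = list(n_agents = 8, agent_radius = 10, frame_rate = 4,
                   duration = 60, rate_per_pair = 1,
                   frame_width = 640, frame_height = 480,
                   background_noise_sd = 0, agent_spacing = 72),
      litter = list(n_wall = 3, n_system = 5, n_frames = 8,
                    frame_width = 640, frame_height = 480),
      counts = list(
        day_type = "visual", anchor = "14:30:00",
        phase_means = c("Feeding 1" = 25.2, "Resting 1" = 14.0,
                        "Feeding sound" = 23.9, "Resting 2" = 13.1,
                        "Predator cue 1" = 9.3, "Predator cue 2" = 5.0,
                        "Resting 3" = 14.0, "Resting 4" = 19.4,
                        "Feeding 2" = 39.9),
        phase_durations = c(5, 25, 5, 25, 3, 3, 25, 24, 5),
        week_sd = 0.23, nb_dispersion = 10, n_weeks = 10, n_groups = 4)),
    vertical_movement = list(blur_kernel = 5, diff_threshold = 25,
                             agent_radius = 10, max_link_distance = 70,
                             max_gap = 2, frame_rate = 4),
    litter = list(threshold = 25, min_area = 40, max_area = 5000,
                  litter_area = 4),
    stress = list(stressor = "visual", horizon = "short",
                  frustration_anchor = "early", onset = "15:30:00"),
    evaluation = list(tolerance = 0.5))
}

read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$simulate$counts$phase_means))
    cfg$simulate$counts$phase_means <- unlist(cfg$simulate$counts$phase_means)
  cfg
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  utils::modifyList(base, override)
}

write_manifest <- function(out_dir, subcommand, cfg, inputs, outputs,
                           status = "ok") {
  cfg_path <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  man <- list(subcommand = subcommand,
              seed = cfg$seed,
              config_hash = unname(tools::md5sum(cfg_path)),
              package_version = as.character(utils::packageVersion("flockmotion")),
              inputs = inputs, outputs = outputs, status = status)
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", subcommand,
                                                      ".json")),
                       auto_unbox = TRUE)
  invisible(man)
}

scenario_from_config <- function(cfg) {
  v <- cfg$simulate$video
  zm <- stacked_zone_map(v$frame_width, v$frame_height, 4,
                         stairs = c(v$frame_width - 140,
                                    v$frame_height / 2,
                                    v$frame_width - 80, v$frame_height))
  rates <- do.call(rbind, lapply(1:3, function(i)
    data.frame(from = c(i, i + 1L), to = c(i + 1L, i),
               rate = v$rate_per_pair)))
  video_scenario(zonemap = zm, n_agents = v$n_agents,
                 agent_radius = v$agent_radius, frame_rate = v$frame_rate,
                 duration = v$duration, crossing_rates = rates,
                 background_noise_sd = v$background_noise_sd,
                 agent_spacing = v$agent_spacing, seed = cfg$seed)
}

#' Run one pipeline stage (or all of them)
#'
#' Subcommands: `simulate` (synthetic aviary scene + litter scene + weekly
#' count series, with ground truth), `count-movements`, `count-litter`,
#' `evaluate`, `describe`, `friedman`, `stress-fit`, or `all` which chains
#' them. Every stage writes its artifacts and a manifest (inputs, config
#' hash, seed, package version) to `out_dir`; reruns with identical config
#' and seed reproduce identical CSV outputs.
#'
#' @param subcommand stage name (see above).
#' @param out_dir output directory.
#' @param config optional configuration list overriding [default_config()].
#' @param config_path optional JSON configuration file (applied before
#'   `config`).
#' @param seed optional global seed override.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "count-movements",
                                        "count-litter", "evaluate",
                                        "describe", "friedman", "stress-fit"),
                         out_dir, config = NULL, config_path = NULL,
                         seed = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- default_config()
  if (!is.null(config_path)) cfg <- merge_config(cfg, read_config(config_path))
  cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (subcommand == "all")
    c("simulate", "count-movements", "count-litter", "evaluate", "describe",
      "friedman", "stress-fit") else subcommand
  res <- list()
  for (st in stages) {
    r <- tryCatch(run_stage(st, cfg, out_dir), error = function(e) {
      write_manifest(out_dir, st, cfg, inputs = list(), outputs = list(),
                     status = paste("failed:", conditionMessage(e)))
      stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res[[st]] <- r
  }
  invisible(res)
}

run_stage <- function(st, cfg, out_dir) {
  switch(st,
    "simulate" = stage_simulate(cfg, out_dir),
    "count-movements" = stage_count_movements(cfg, out_dir),
    "count-litter" = stage_count_litter(cfg, out_dir),
    "evaluate" = stage_evaluate(cfg, out_dir),
    "describe" = stage_describe(cfg, out_dir),
    "friedman" = stage_friedman(cfg, out_dir),
    "stress-fit" = stage_stress_fit(cfg, out_dir))
}

stage_simulate <- function(cfg, out_dir) {
  sc <- scenario_from_config(cfg)
  truth <- simulate_crossing_schedule(sc)
  fs <- render_video(sc, truth)
  frames_dir <- file.path(out_dir, "frames")
  write_frames(fs, frames_dir)
  write_zone_annotation(sc$zonemap, file.path(out_dir, "zones.json"))
  utils::write.csv(truth$events, file.path(out_dir, "truth_events.csv"),
                   row.names = FALSE, quote = FALSE)
  occ <- as.data.frame(truth$occupancy)
  occ <- cbind(frame = seq_len(nrow(occ)), occ)
  utils::write.csv(occ, file.path(out_dir, "truth_occupancy.csv"),
                   row.names = FALSE, quote = FALSE)

  lt <- cfg$simulate$litter
  lzm <- litter_zone_map(lt$frame_width, lt$frame_height)
  scene <- simulate_litter_scene(lt$n_wall, lt$n_system, lzm,
                                 n_frames = lt$n_frames, seed = cfg$seed)
  write_frames(scene$frames, file.path(out_dir, "litter_frames"))
  write_pgm(scene$background, file.path(out_dir, "litter_background.pgm"))
  write_zone_annotation(lzm, file.path(out_dir, "litter_zones.json"))
  utils::write.csv(scene$truth, file.path(out_dir, "truth_litter_counts.csv"),
                   row.names = FALSE, quote = FALSE)

  cs <- cfg$simulate$counts
  params <- count_sim_params(phase_means = cs$phase_means,
                             phase_durations = stats::setNames(
                               cs$phase_durations, names(cs$phase_means)),
                             week_sd = cs$week_sd,
                             nb_dispersion = cs$nb_dispersion,
                             n_weeks = cs$n_weeks, n_groups = cs$n_groups,
                             day_type = cs$day_type,
                             anchor_clock = clock_to_seconds(cs$anchor),
                             seed = cfg$seed)
  series <- simulate_count_series(params)
  write_counts(series[, setdiff(names(series), "phase")],
               file.path(out_dir, "weekly_counts.csv"))
  write_manifest(out_dir, "simulate", cfg, inputs = list(),
                 outputs = list("frames/", "zones.json", "truth_events.csv",
                                "truth_occupancy.csv", "litter_frames/",
                                "weekly_counts.csv"))
  list(scenario = sc, truth = truth, litter = scene, series = series)
}

stage_count_movements <- function(cfg, out_dir) {
  fs <- read_frames(file.path(out_dir, "frames"))
  zm <- read_zone_annotation(file.path(out_dir, "zones.json"))
  res <- count_movements(fs, zm, cfg$vertical_movement)
  utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  write_counts(res$minute_counts, file.path(out_dir, "movement_counts.csv"))
  write_manifest(out_dir, "count-movements", cfg,
                 inputs = list("frames/", "zones.json"),
                 outputs = list("events.csv", "movement_counts.csv"))
  res
}

stage_count_litter <- function(cfg, out_dir) {
  fs <- read_frames(file.path(out_dir, "litter_frames"))
  bg <- read_pgm(file.path(out_dir, "litter_background.pgm"))
  zm <- read_zone_annotation(file.path(out_dir, "litter_zones.json"))
  grid <- litter_grid(zm, litter_area = cfg$litter$litter_area)
  res <- count_litter(fs, bg, grid, cfg$litter)
  utils::write.csv(res$frame_counts, file.path(out_dir, "litter_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  sec <- aggregate_series(res$frame_counts, fs$frame_rate, interval_s = 1)
  write_counts(sec, file.path(out_dir, "litter_counts_per_second.csv"))
  hm <- occupancy_heatmap(res$detections, frame_width = fs$width,
                          frame_height = fs$height)
  utils::write.table(hm, file.path(out_dir, "litter_heatmap.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  write_manifest(out_dir, "count-litter", cfg,
                 inputs = list("litter_frames/", "litter_background.pgm",
                               "litter_zones.json"),
                 outputs = list("litter_counts.csv",
                                "litter_counts_per_second.csv",
                                "litter_heatmap.csv"))
  res
}

stage_evaluate <- function(cfg, out_dir) {
  pred <- utils::read.csv(file.path(out_dir, "events.csv"),
                          stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(out_dir, "truth_events.csv"),
                           stringsAsFactors = FALSE)
  truth$direction <- ifelse(truth$to_zone < truth$from_zone, "up", "down")
  cc_mv <- match_events(pred, truth, cfg$evaluation$tolerance)
  pred_lit <- utils::read.csv(file.path(out_dir, "litter_counts.csv"),
                              stringsAsFactors = FALSE)
  true_lit <- utils::read.csv(file.path(out_dir, "truth_litter_counts.csv"),
                              stringsAsFactors = FALSE)
  m <- merge(pred_lit, true_lit, by = c("frame", "zone_label"),
             suffixes = c("_pred", "_true"))
  cc_lit <- count_confusion(m$count_pred, m$count_true)
  rows <- data.frame(video_id = c("synthetic-aviary", "synthetic-litter"),
                     measure = c("vertical_movement", "litter_zone_count"),
                     TP = c(cc_mv$TP, cc_lit$TP), FP = c(cc_mv$FP, cc_lit$FP),
                     FN = c(cc_mv$FN, cc_lit$FN))
  rep <- evaluation_report(rows, csv_path = file.path(out_dir, "evaluation.csv"),
                           json_path = file.path(out_dir, "evaluation.json"))
  write_manifest(out_dir, "evaluate", cfg,
                 inputs = list("events.csv", "truth_events.csv",
                               "litter_counts.csv", "truth_litter_counts.csv"),
                 outputs = list("evaluation.csv", "evaluation.json"))
  rep
}

stage_describe <- function(cfg, out_dir) {
  series <- read_counts(file.path(out_dir, "weekly_counts.csv"))
  sched <- build_schedule(cfg$simulate$counts$day_type)
  lab <- label_minutes(series, sched)
  desc <- weekly_descriptives(lab)
  utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "describe", cfg,
                 inputs = list("weekly_counts.csv"),
                 outputs = list("descriptives.csv"))
  desc
}

stage_friedman <- function(cfg, out_dir) {
  series <- read_counts(file.path(out_dir, "weekly_counts.csv"))
  sched <- build_schedule(cfg$simulate$counts$day_type)
  lab <- label_minutes(series, sched)
  mat <- friedman_matrix(lab)
  ft <- friedman_block_test(mat)
  ph <- posthoc_pairs(mat, seed = cfg$seed)
  jsonlite::write_json(list(chi2 = ft$chi2, df = ft$df, p = ft$p, W = ft$W,
                            n_blocks = ft$n_blocks,
                            posthoc = ph),
                       file.path(out_dir, "friedman.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "friedman", cfg,
                 inputs = list("weekly_counts.csv"),
                 outputs = list("friedman.json"))
  list(test = ft, posthoc = ph)
}

stage_stress_fit <- function(cfg, out_dir) {
  series <- read_counts(file.path(out_dir, "weekly_counts.csv"))
  spec <- window_spec(cfg$stress$stressor, cfg$stress$horizon,
                      cfg$stress$frustration_anchor)
  lab <- select_windows(series, spec,
                        onset_clock = clock_to_seconds(cfg$stress$onset))
  fit <- fit_nb_glmm(lab)
  rep <- phase_report(fit)
  utils::write.csv(rep, file.path(out_dir, "stress_phase_report.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(coefficients = as.list(fit$coefficients),
                            dispersion = fit$dispersion,
                            week_sd = fit$week_sd,
                            week_intercepts = fit$week_intercepts,
                            log_likelihood = fit$log_likelihood,
                            converged = fit$converged,
                            gradient_norm = fit$gradient_norm),
                       file.path(out_dir, "stress_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "stress-fit", cfg,
                 inputs = list("weekly_counts.csv"),
                 outputs = list("stress_phase_report.csv", "stress_fit.json"))
  fit
}
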