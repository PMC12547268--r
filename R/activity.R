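#' Activity-category schedule for an observation day
#'
#' Each observation day is partitioned into named, contiguous activity
#' categories (feeding, feeding sound, resting, and the stress-specific
#' categories) that are the statistical unit of the weekly-consistency
#' analysis. Default schedules:
#'
#' * visual day (anchor 14:30): Feeding 1 (5), Resting 1 (25), Feeding sound
#'   (5), Resting 2 (25), Predator cue 1 (3), Predator cue 2 (3), Resting 3
#'   (25), Resting 4 (24), Feeding 2 (5) — the predator cue starts at 15:30.
#' * auditory day (anchor 14:30): Feeding 1 (5), Resting 1 (25), Feeding
#'   sound (5), Resting 2 (25), Thunder sound (1), Resting 3 (27), Resting 4
#'   (26), Feeding 2 (5).
#' * frustrative day (anchor 09:00): Resting 1 (30), Resting 2 (30),
#'   Frustration 1–4 (15 each), Feeding 1 (5), Resting 3 (30), Resting 4
#'   (30) — delayed feeding starts at 10:00.
#'
#' @param day_type `"visual"`, `"auditory"` or `"frustrative"`.
#' @param config optional override: list with `anchor` (clock string or
#'   seconds) and `categories` (data frame `name, duration_min`).
#' @return data frame `name, start_clock, duration_min, end_clock`
#'   (class `activity_schedule`), sequential and contiguous.
#' @export
build_schedule <- function(day_type, config = NULL) {
  defaults <- list(
    visual = list(anchor = "14:30:00", categories = data.frame(
      name = c("Feeding 1", "Resting 1", "Feeding sound", "Resting 2",
               "Predator cue 1", "Predator cue 2", "Resting 3", "Resting 4",
               "Feeding 2"),
      duration_min = c(5, 25, 5, 25, 3, 3, 25, 24, 5))),
    auditory = list(anchor = "14:30:00", categories = data.frame(
      name = c("Feeding 1", "Resting 1", "Feeding sound", "Resting 2",
               "Thunder sound", "Resting 3", "Resting 4", "Feeding 2"),
      duration_min = c(5, 25, 5, 25, 1, 27, 26, 5))),
    frustrative = list(anchor = "09:00:00", categories = data.frame(
      name = c("Resting 1", "Resting 2", "Frustration 1", "Frustration 2",
               "Frustration 3", "Frustration 4", "Feeding 1", "Resting 3",
               "Resting 4"),
      duration_min = c(30, 30, 15, 15, 15, 15, 5, 30, 30))))
  if (is.null(config)) {
    if (!day_type %in% names(defaults))
      stop("no default schedule for day_type '", day_type, "'")
    config <- defaults[[day_type]]
  }
  anchor <- config$anchor
  if (is.character(anchor)) anchor <- clock_to_seconds(anchor)
  cats <- config$categories
  if (any(cats$duration_min <= 0)) stop("category durations must be > 0")
  start <- anchor + 60 * cumsum(c(0, cats$duration_min[-nrow(cats)]))
  sched <- data.frame(name = cats$name, start_clock = start,
                      duration_min = cats$duration_min,
                      end_clock = start + 60 * cats$duration_min,
                      stringsAsFactors = FALSE)
  # contiguity is by construction; still guard against a bad override
  if (nrow(sched) > 1 &&
      any(abs(sched$start_clock[-1] - sched$end_clock[-nrow(sched)]) > 1e-9))
    stop("schedule has gaps or overlaps")
  class(sched) <- c("activity_schedule", "data.frame")
  sched
}

#' Label per-minute records with their activity category
#'
#' A minute starting exactly at a category boundary belongs to the category
#' that starts there. Records outside the schedule window are tagged
#' `"unscheduled"` with a warning.
#'
#' @param records a `count_records` data frame (60-s intervals).
#' @param schedule an [build_schedule()] output.
#' @return `records` with an added `activity` column.
#' @export
label_minutes <- function(records, schedule) {
  lab <- rep("unscheduled", nrow(records))
  for (i in seq_len(nrow(schedule))) {
    sel <- records$clock_time >= schedule$start_clock[i] &
      records$clock_time < schedule$end_clock[i]
    lab[sel] <- schedule$name[i]
  }
  if (any(lab == "unscheduled") && nrow(records))
    warning(sum(lab == "unscheduled"), " record(s) outside the schedule ",
            "window tagged 'unscheduled'")
  records$activity <- lab
  records
}

#' Quartile coefficient of dispersion, in percent
#'
#' `100 * (Q3 - Q1) / (Q3 + Q1)`: a scale-free between-week variability
#' measure (low QCD = high weekly consistency). Undefined when Q1 + Q3 = 0.
#'
#' @param q1,q3 first and third quartiles (nonnegative).
#' @return QCD in percent, `NA` (with warning) when undefined.
#' @export
qcd <- function(q1, q3) {
  if (q1 + q3 == 0) {
    warning("QCD undefined: Q1 + Q3 = 0")
    return(NA_real_)
  }
  100 * (q3 - q1) / (q3 + q1)
}

#' Weekly-consistency descriptives per activity category
#'
#' Aggregation order follows the study design: per minute, values are first
#' averaged across experimental groups; the per-week summary of an activity
#' is then the mean (config-switchable to median) of its per-minute values;
#' the table row summarises the per-week summaries across weeks with median,
#' Q1, Q3 (linear-interpolation quantiles, type 7), IQR = Q3 - Q1, QCD, and
#' the weekly minimum and maximum.
#'
#' @param labeled `count_records` with an `activity` column (from
#'   [label_minutes()]).
#' @param inner_stat `"mean"` (default) or `"median"` for the per-week
#'   within-activity summary.
#' @return data frame with one row per activity: `activity, median, Q1, Q3,
#'   IQR, QCD, weekly_min, weekly_max, n_weeks`.
#' @export
weekly_descriptives <- function(labeled, inner_stat = c("mean", "median")) {
  inner_stat <- match.arg(inner_stat)
  inner <- if (inner_stat == "mean") mean else stats::median
  labeled <- labeled[labeled$activity != "unscheduled", , drop = FALSE]
  if (!nrow(labeled)) stop("no labeled records")
  # average across groups per (week, activity, minute)
  g <- stats::aggregate(value ~ week + activity + clock_time, data = labeled,
                        FUN = mean)
  # per-week summary per activity
  wk <- stats::aggregate(value ~ week + activity, data = g, FUN = inner)
  out <- do.call(rbind, lapply(split(wk, wk$activity), function(d) {
    qs <- stats::quantile(d$value, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(activity = d$activity[1], median = qs[2], Q1 = qs[1],
               Q3 = qs[3], IQR = qs[3] - qs[1],
               QCD = if (qs[1] + qs[3] > 0) qcd(qs[1], qs[3]) else NA_real_,
               weekly_min = min(d$value), weekly_max = max(d$value),
               n_weeks = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# within-block mid-ranks of a blocks x treatments matrix
block_ranks <- function(mat) t(apply(mat, 1, rank))

#' Week-blocked Friedman test with Kendall's W
#'
#' Within-block mid-ranks with tie correction; the statistic is
#' chi^2_F = (k - 1) * sum_j (R_j - n(k+1)/2)^2 / (sum r_ij^2 - n k (k+1)^2 / 4)
#' with df = k - 1, p from the chi-squared reference distribution, and
#' Kendall's concordance W = chi^2_F / (n (k - 1)).
#'
#' @param mat numeric blocks x treatments matrix (weeks x activities), no
#'   missing cells.
#' @param p_method `"asymptotic"` (chi-squared reference, default) or
#'   `"exact"`: full enumeration of the (k!)^n equally likely within-block
#'   orderings of the observed values (feasible for small designs only).
#' @return list `chi2, df, p, W, n_blocks, k` of class `friedman_result`.
#' @export
friedman_block_test <- function(mat, p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells in Friedman matrix (no imputation)")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments")
  stat_of <- function(m) {
    r <- block_ranks(m)
    denom <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (denom <= 0) 0
    else (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  }
  chi2 <- stat_of(mat)
  p <- if (p_method == "asymptotic") {
    stats::pchisq(chi2, k - 1, lower.tail = FALSE)
  } else {
    if (factorial(k)^n > 2e6)
      stop("exact p infeasible for this design; use p_method = 'asymptotic'")
    perms <- permutations_of(k)
    combos <- expand.grid(rep(list(seq_len(nrow(perms))), n))
    count <- 0L
    for (i in seq_len(nrow(combos))) {
      m <- mat
      for (b in seq_len(n)) m[b, ] <- mat[b, perms[combos[i, b][[1]], ]]
      if (stat_of(m) >= chi2 - 1e-12) count <- count + 1L
    }
    count / nrow(combos)
  }
  structure(list(chi2 = chi2, df = k - 1, p = p, p_method = p_method,
                 W = chi2 / (n * (k - 1)), n_blocks = n, k = k),
            class = "friedman_result")
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi2(%d) = %.2f, p = %.3g, Kendall W = %.2f (%d blocks)\n",
              x$df, x$chi2, x$p, x$W, x$n_blocks))
  invisible(x)
}

#' Exact all-pairs post hoc comparisons with FDR control
#'
#' For each treatment pair the statistic is the absolute sum over blocks of
#' the within-block rank difference between the two treatments. Its exact
#' null is obtained by full enumeration of the 2^n within-block orderings of
#' the pair (swapping the pair's values within a block negates that block's
#' rank difference) when the block count is <= `exact_max_blocks`, else by
#' seeded Monte-Carlo sign flips. P-values are Benjamini-Hochberg adjusted
#' across pairs.
#'
#' @param mat blocks x treatments matrix with column names.
#' @param exact_max_blocks enumeration limit (default 10).
#' @param n_mc Monte-Carlo permutations beyond the limit.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return data frame `pair, statistic, raw_p, adjusted_p`.
#' @export
posthoc_pairs <- function(mat, exact_max_blocks = 10, n_mc = 10000,
                          seed = 1L) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("T", seq_len(k))
  r <- block_ranks(mat)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(pi) {
    j1 <- pairs[1, pi]; j2 <- pairs[2, pi]
    d <- r[, j1] - r[, j2]
    obs <- abs(sum(d))
    if (n <= exact_max_blocks) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      null_stats <- abs(signs %*% d)
      p <- mean(null_stats >= obs - 1e-12)
    } else {
      set.seed(seed + pi)
      flips <- matrix(sample(c(-1, 1), n * n_mc, replace = TRUE), n_mc, n)
      null_stats <- abs(flips %*% d)
      p <- (1 + sum(null_stats >= obs - 1e-12)) / (n_mc + 1)
    }
    data.frame(pair = paste(colnames(mat)[j1], colnames(mat)[j2], sep = " vs "),
               statistic = obs, raw_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = "BH")
  out
}

#' Weeks x activities summary matrix for the Friedman analysis
#'
#' Builds the block matrix consumed by [friedman_block_test()] and
#' [posthoc_pairs()] from labelled records: values averaged across groups
#' per minute, then summarised per week per activity.
#'
#' @inheritParams weekly_descriptives
#' @return numeric weeks x activities matrix.
#' @export
friedman_matrix <- function(labeled, inner_stat = c("mean", "median")) {
  inner_stat <- match.arg(inner_stat)
  inner <- if (inner_stat == "mean") mean else stats::median
  labeled <- labeled[labeled$activity != "unscheduled", , drop = FALSE]
  g <- stats::aggregate(value ~ week + activity + clock_time, data = labeled,
                        FUN = mean)
  wk <- stats::aggregate(value ~ week + activity, data = g, FUN = inner)
  weeks <- sort(unique(wk$week))
  acts <- unique(wk$activity)
  mat <- matrix(NA_real_, length(weeks), length(acts),
                dimnames = list(weeks, acts))
  for (i in seq_len(nrow(wk)))
    mat[as.character(wk$week[i]), wk$activity[i]] <- wk$value[i]
  mat
}
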