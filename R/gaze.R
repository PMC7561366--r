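# Scoring of raw gaze streams: trial validity, oculomotor-orienting saccadic
# reaction times (SRT), and the normalized attention-disengagement dwell-time
# index.
#
# Coordinates are degrees of visual angle in a screen-centered frame
# (x rightward, y upward); time is milliseconds from trial start. Areas of
# interest (AOIs) are closed rectangles.

#' Scoring configuration for the gaze tasks
#'
#' Defaults are the overlap-paradigm analysis settings: saccades are accepted
#' in a 150-1000 ms window after the lateral-stimulus onset (an 850-ms
#' normalization range for the dwell index), central fixation must cover more
#' than 70\% of valid pre-shift samples, gaps of missing data longer than
#' 200 ms invalidate a trial, and participants need at least 4 scorable
#' orienting trials / 3 scorable disengagement trials per stimulus condition.
#'
#' @param fixation_min_fraction Minimum fraction of valid pre-shift samples
#'   inside the central AOI (strictly greater than).
#' @param max_gap_ms Longest tolerated run of missing/invalid data (ms).
#' @param window_start_ms,window_end_ms Accepted saccade window relative to
#'   lateral onset (ms).
#' @param norm_range_ms Normalization range of the dwell index; must equal
#'   \code{window_end_ms - window_start_ms}.
#' @param min_orienting_trials Minimum scorable orienting trials for
#'   participant inclusion.
#' @param min_trials_per_condition Minimum scorable disengagement trials per
#'   stimulus condition.
#' @param screen_half_x_deg,screen_half_y_deg Half-extent of the calibrated
#'   screen (degrees); gaze outside it counts as off-screen.
#' @return An object of class \code{scoring_config}.
#' @export
scoring_config <- function(fixation_min_fraction = 0.7, max_gap_ms = 200,
                           window_start_ms = 150, window_end_ms = 1000,
                           norm_range_ms = 850,
                           min_orienting_trials = 4L,
                           min_trials_per_condition = 3L,
                           screen_half_x_deg = 13.5,
                           screen_half_y_deg = 10.5) {
  .assert(isTRUE(all.equal(window_end_ms - window_start_ms, norm_range_ms)),
          "window_end_ms - window_start_ms must equal norm_range_ms")
  .assert(window_start_ms > 0 && max_gap_ms > 0, "windows must be positive")
  structure(list(
    fixation_min_fraction = fixation_min_fraction, max_gap_ms = max_gap_ms,
    window_start_ms = window_start_ms, window_end_ms = window_end_ms,
    norm_range_ms = norm_range_ms,
    min_orienting_trials = as.integer(min_orienting_trials),
    min_trials_per_condition = as.integer(min_trials_per_condition),
    screen_half_x_deg = screen_half_x_deg,
    screen_half_y_deg = screen_half_y_deg
  ), class = "scoring_config")
}

#' Rectangular area of interest
#'
#' @param center_x,center_y Center in degrees of visual angle.
#' @param width,height Extent in degrees.
#' @return An object of class \code{aoi}.
#' @export
aoi <- function(center_x, center_y, width, height) {
  .assert(width > 0 && height > 0, "AOI width and height must be positive")
  structure(list(center_x = center_x, center_y = center_y,
                 width = width, height = height), class = "aoi")
}

#' Test which gaze samples fall inside an AOI (closed bounds)
#'
#' @param a An \code{\link{aoi}}.
#' @param x,y Gaze coordinates in degrees.
#' @return Logical vector.
#' @export
aoi_contains <- function(a, x, y) {
  abs(x - a$center_x) <= a$width / 2 & abs(y - a$center_y) <= a$height / 2
}

GAZE_CONDITIONS <- c("target", "happy", "fearful", "nonface")

#' Read gaze samples and trial events into trial records
#'
#' The gaze file is a CSV with columns \code{trial_id}, \code{task}
#' (\code{orienting} or \code{disengagement}), \code{condition},
#' \code{time_ms}, \code{x}, \code{y}, \code{valid}; the events sidecar has
#' one row per trial: \code{trial_id}, \code{lateral_onset_ms}, and AOI
#' geometry columns \code{central_x}, \code{central_y}, \code{central_w},
#' \code{central_h}, \code{lateral_x}, \code{lateral_y}, \code{lateral_w},
#' \code{lateral_h}.
#'
#' @param gaze_path Path to the gaze CSV.
#' @param events_path Path to the events CSV.
#' @return A list of trial records; each has \code{trial_id}, \code{task},
#'   \code{condition}, \code{central_aoi}, \code{lateral_aoi},
#'   \code{lateral_onset_ms}, and \code{samples} (data.frame sorted by time).
#' @export
read_gaze_file <- function(gaze_path, events_path) {
  gaze <- utils::read.csv(gaze_path, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  need_g <- c("trial_id", "task", "condition", "time_ms", "x", "y", "valid")
  need_e <- c("trial_id", "lateral_onset_ms", "central_x", "central_y",
              "central_w", "central_h", "lateral_x", "lateral_y",
              "lateral_w", "lateral_h")
  .assert(all(need_g %in% names(gaze)), "gaze file missing columns: %s",
          paste(setdiff(need_g, names(gaze)), collapse = ", "))
  .assert(all(need_e %in% names(events)), "events file missing columns: %s",
          paste(setdiff(need_e, names(events)), collapse = ", "))
  bad_cond <- setdiff(unique(gaze$condition), GAZE_CONDITIONS)
  .assert(length(bad_cond) == 0L, "unknown condition(s): %s",
          paste(bad_cond, collapse = ", "))

  trial_ids <- unique(gaze$trial_id)
  orphans <- setdiff(trial_ids, events$trial_id)
  .assert(length(orphans) == 0L, "trial(s) missing an events row: %s",
          paste(orphans, collapse = ", "))

  lapply(trial_ids, function(id) {
    s <- gaze[gaze$trial_id == id, , drop = FALSE]
    .assert(!is.unsorted(s$time_ms, strictly = TRUE),
            "timestamps not strictly increasing in trial %s", id)
    e <- events[match(id, events$trial_id), ]
    task <- unique(s$task)
    condition <- unique(s$condition)
    .assert(length(task) == 1L && length(condition) == 1L,
            "inconsistent task/condition labels in trial %s", id)
    .assert((condition == "target") == (task == "orienting"),
            "condition 'target' is reserved for orienting trials (trial %s)",
            id)
    list(trial_id = id, task = task, condition = condition,
         central_aoi = aoi(e$central_x, e$central_y, e$central_w,
                           e$central_h),
         lateral_aoi = aoi(e$lateral_x, e$lateral_y, e$lateral_w,
                           e$lateral_h),
         lateral_onset_ms = e$lateral_onset_ms,
         samples = s[order(s$time_ms),
                     c("time_ms", "x", "y", "valid"), drop = FALSE])
  })
}

# Longest run of missing/invalid samples (ms) within the sample window
# [t0, t1], measured between the timestamps bracketing the run.
longest_gap_ms <- function(samples, t0, t1) {
  s <- samples[samples$time_ms >= t0 & samples$time_ms <= t1, , drop = FALSE]
  if (nrow(s) == 0L) return(t1 - t0)
  bad <- !s$valid | is.na(s$x) | is.na(s$y)
  if (!any(bad)) return(0)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- which(r$values)
  max(vapply(runs, function(k) {
    lo <- if (begins[k] > 1L) s$time_ms[begins[k] - 1L] else t0
    hi <- if (ends[k] < nrow(s)) s$time_ms[ends[k] + 1L] else t1
    hi - lo
  }, numeric(1)))
}

#' Score the validity of one trial and locate its gaze shift
#'
#' A trial is invalid when central fixation covers at most 70\% of the valid
#' samples before the shift (or before the window end if no shift occurred),
#' when any missing-data run in the analysis period exceeds the gap limit,
#' or when the central-to-lateral transition falls inside a missing-data run.
#' Shifts landing off-screen before reaching the lateral AOI, or earlier /
#' later than the accepted saccade window, are excluded with their own
#' reasons.
#'
#' @param trial A trial record (see \code{\link{read_gaze_file}}).
#' @param cfg A \code{\link{scoring_config}}.
#' @return A list with \code{status} (\code{"valid_shift"},
#'   \code{"valid_no_shift"}, or \code{"invalid"}), \code{reason} (for
#'   invalid trials: \code{insufficient_fixation}, \code{data_gap},
#'   \code{shift_in_gap}, \code{off_screen}, \code{too_early},
#'   \code{too_late}), and \code{saccade_time_ms} (relative to lateral onset;
#'   present iff \code{valid_shift}).
#' @export
validate_trial <- function(trial, cfg = scoring_config()) {
  s <- trial$samples
  onset <- trial$lateral_onset_ms
  analysis_end <- onset + cfg$window_end_ms
  valid <- s$valid & !is.na(s$x) & !is.na(s$y)

  in_lat <- valid & aoi_contains(trial$lateral_aoi, s$x, s$y) &
    s$time_ms > onset
  in_cen <- valid & aoi_contains(trial$central_aoi, s$x, s$y)
  on_screen <- abs(s$x) <= cfg$screen_half_x_deg &
    abs(s$y) <= cfg$screen_half_y_deg

  first_lat <- if (any(in_lat)) which(in_lat)[1L] else NA_integer_
  last_cen <- if (!is.na(first_lat)) {
    pre <- which(in_cen & seq_along(in_cen) < first_lat)
    if (length(pre) > 0L) pre[length(pre)] else NA_integer_
  } else NA_integer_

  # off-screen excursion before the lateral AOI is reached
  left_screen <- valid & !on_screen & s$time_ms > onset &
    s$time_ms <= analysis_end
  if (!is.na(first_lat)) {
    left_screen <- left_screen & seq_along(valid) < first_lat
  }

  shift_end_ms <- if (!is.na(first_lat)) s$time_ms[first_lat] else
    analysis_end

  # >70% central fixation among valid samples from trial start to the shift
  # (or to the window end when no shift occurred)
  pre <- valid & s$time_ms <= shift_end_ms
  fix_frac <- if (sum(pre) > 0L) sum(in_cen & pre) / sum(pre) else 0
  if (fix_frac <= cfg$fixation_min_fraction) {
    return(list(status = "invalid", reason = "insufficient_fixation",
                saccade_time_ms = NA_real_))
  }

  if (longest_gap_ms(s, 0, min(shift_end_ms, analysis_end)) >
      cfg$max_gap_ms) {
    return(list(status = "invalid", reason = "data_gap",
                saccade_time_ms = NA_real_))
  }

  if (!is.na(first_lat)) {
    if (is.na(last_cen)) {
      return(list(status = "invalid", reason = "shift_in_gap",
                  saccade_time_ms = NA_real_))
    }
    between <- seq_along(valid) > last_cen & seq_along(valid) < first_lat
    if (any(between & !valid)) {
      return(list(status = "invalid", reason = "shift_in_gap",
                  saccade_time_ms = NA_real_))
    }
    if (any(left_screen)) {
      return(list(status = "invalid", reason = "off_screen",
                  saccade_time_ms = NA_real_))
    }
    # saccade time: last gaze point on the central stimulus preceding the
    # saccade toward the lateral stimulus
    x_ms <- s$time_ms[last_cen] - onset
    if (x_ms < cfg$window_start_ms) {
      return(list(status = "invalid", reason = "too_early",
                  saccade_time_ms = NA_real_))
    }
    if (x_ms > cfg$window_end_ms) {
      return(list(status = "invalid", reason = "too_late",
                  saccade_time_ms = NA_real_))
    }
    return(list(status = "valid_shift", reason = NA_character_,
                saccade_time_ms = x_ms))
  }
  list(status = "valid_no_shift", reason = NA_character_,
       saccade_time_ms = NA_real_)
}

#' Saccadic reaction time of an orienting trial
#'
#' The SRT is the time of the first sample inside the target (lateral) AOI
#' minus the target onset. Shifts earlier than the window start, later than
#' the window end, or preceded by an off-screen excursion are excluded.
#'
#' @param trial An orienting trial record.
#' @param cfg A \code{\link{scoring_config}}.
#' @return A list with \code{srt_ms} (NA when excluded) and \code{status}
#'   (\code{"valid"} or the exclusion reason).
#' @export
orienting_latency <- function(trial, cfg = scoring_config()) {
  .assert(identical(trial$task, "orienting"),
          "orienting_latency expects an orienting trial")
  v <- validate_trial(trial, cfg)
  if (v$status == "invalid") {
    return(list(srt_ms = NA_real_, status = v$reason))
  }
  if (v$status == "valid_no_shift") {
    return(list(srt_ms = NA_real_, status = "too_late"))
  }
  s <- trial$samples
  valid <- s$valid & !is.na(s$x) & !is.na(s$y)
  in_lat <- valid & aoi_contains(trial$lateral_aoi, s$x, s$y) &
    s$time_ms > trial$lateral_onset_ms
  srt <- s$time_ms[which(in_lat)[1L]] - trial$lateral_onset_ms
  if (srt < cfg$window_start_ms) {
    return(list(srt_ms = NA_real_, status = "too_early"))
  }
  if (srt > cfg$window_end_ms) {
    return(list(srt_ms = NA_real_, status = "too_late"))
  }
  list(srt_ms = srt, status = "valid")
}

#' Dwell-time contribution of one disengagement trial
#'
#' Maps a saccade time x (ms after distractor onset) linearly onto
#' \code{[0, 1]}: \code{1 - (window_end - x) / norm_range}. With the default
#' window this is \code{1 - (1000 - x)/850}, so the shortest acceptable
#' saccade (150 ms) contributes 0 and a trial without a shift (entered at
#' x = 1000 ms) contributes 1.
#'
#' @param x Saccade time in ms, within the accepted window.
#' @param cfg A \code{\link{scoring_config}}.
#' @return Dwell contribution in \code{[0, 1]}.
#' @export
dwell_contribution <- function(x, cfg = scoring_config()) {
  .assert(all(x >= cfg$window_start_ms & x <= cfg$window_end_ms),
          "saccade time outside [%g, %g] ms must be excluded by the caller",
          cfg$window_start_ms, cfg$window_end_ms)
  1 - (cfg$window_end_ms - x) / cfg$norm_range_ms
}

#' Dwell-time index of one stimulus condition
#'
#' Mean dwell contribution over the scorable trials of one condition: trials
#' with a gaze shift enter at their saccade time, trials without a shift
#' enter at the window end (contribution 1), non-scorable trials are
#' excluded. Conditions with fewer than the minimum number of scorable
#' trials are excluded.
#'
#' @param scores List of trial scores (from \code{\link{validate_trial}}).
#' @param cfg A \code{\link{scoring_config}}.
#' @return A list with \code{index} (NA when excluded), \code{n_scorable},
#'   and \code{included}.
#' @export
dwell_index_for_condition <- function(scores, cfg = scoring_config()) {
  xs <- unlist(lapply(scores, function(sc) {
    if (sc$status == "valid_shift") sc$saccade_time_ms
    else if (sc$status == "valid_no_shift") cfg$window_end_ms
    else NULL
  }))
  n <- length(xs)
  if (n < cfg$min_trials_per_condition) {
    return(list(index = NA_real_, n_scorable = n, included = FALSE))
  }
  list(index = mean(dwell_contribution(xs, cfg)), n_scorable = n,
       included = TRUE)
}

#' Aggregate all scored trials of one participant
#'
#' The orienting latency is the mean SRT over scorable orienting trials
#' (participant included only with at least \code{min_orienting_trials} of
#' them). The dwell index is the unweighted mean of the per-condition
#' dwell indices (included only when every disengagement condition has at
#' least \code{min_trials_per_condition} scorable trials).
#'
#' @param trials List of trial records for one participant.
#' @param cfg A \code{\link{scoring_config}}.
#' @param dwell_conditions Stimulus conditions entering the dwell mean.
#' @return A list with \code{orienting_latency_ms}, \code{n_orienting_trials},
#'   \code{included_orienting}, \code{dwell_index_by_condition},
#'   \code{dwell_index}, \code{included_dwell}, and \code{trial_scores}.
#' @export
aggregate_participant <- function(trials, cfg = scoring_config(),
                                  dwell_conditions = c("happy", "fearful",
                                                       "nonface")) {
  tasks <- vapply(trials, `[[`, character(1), "task")

  srts <- numeric(0)
  scores <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    if (tasks[i] == "orienting") {
      r <- orienting_latency(trials[[i]], cfg)
      scores[[i]] <- list(status = if (is.na(r$srt_ms)) "invalid"
                          else "valid_shift",
                          reason = if (r$status == "valid") NA_character_
                          else r$status,
                          saccade_time_ms = r$srt_ms)
      if (!is.na(r$srt_ms)) srts <- c(srts, r$srt_ms)
    } else {
      scores[[i]] <- validate_trial(trials[[i]], cfg)
    }
  }

  conds <- vapply(trials, `[[`, character(1), "condition")
  by_cond <- lapply(dwell_conditions, function(cc) {
    dwell_index_for_condition(
      scores[tasks == "disengagement" & conds == cc], cfg)
  })
  names(by_cond) <- dwell_conditions
  all_in <- all(vapply(by_cond, `[[`, logical(1), "included"))

  list(
    orienting_latency_ms = if (length(srts) > 0L) mean(srts) else NA_real_,
    n_orienting_trials = length(srts),
    included_orienting = length(srts) >= cfg$min_orienting_trials,
    dwell_index_by_condition = vapply(by_cond, `[[`, numeric(1), "index"),
    dwell_index = if (all_in)
      mean(vapply(by_cond, `[[`, numeric(1), "index")) else NA_real_,
    included_dwell = all_in,
    trial_scores = scores
  )
}
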