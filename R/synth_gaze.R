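# Synthetic gaze-stream generator with per-trial ground truth.
#
# Each trial fixates the central AOI with Gaussian scatter and, unless it is
# a no-shift trial, steps to the lateral AOI center at the drawn latency
# after the lateral-stimulus onset. Missing-data gaps can be injected as
# runs of invalid samples.

#' Specification of a synthetic gaze session
#'
#' @param n_orienting_trials Number of oculomotor-orienting trials.
#' @param n_disengagement_per_condition Disengagement trials per stimulus
#'   condition (happy, fearful, nonface).
#' @param latency_mean_ms,latency_sd_ms Normal distribution of true saccade
#'   latencies, truncated to the scoring window.
#' @param p_no_shift Probability that a disengagement trial has no saccade.
#' @param fixation_noise_deg SD of Gaussian scatter around fixation targets.
#' @param gap_prob Probability of injecting a missing-data gap into a trial.
#' @param gap_dur_ms Length-2 range of injected gap durations (ms).
#' @param gap_start_ms Gap start time within the trial (ms from trial start);
#'   the default places it before the lateral onset so injected gaps trigger
#'   the data-gap rule rather than the shift-in-gap rule.
#' @param lateral_onset_ms Lateral stimulus onset relative to trial start.
#' @param trial_len_ms Total sampled trial duration.
#' @param sample_rate_hz Nominal gaze sampling rate.
#' @param central_aoi,lateral_aoi \code{\link{aoi}}s used for both the
#'   simulation and the events table.
#' @param seed RNG seed.
#' @return An object of class \code{gaze_spec}.
#' @export
gaze_spec <- function(n_orienting_trials = 32L,
                      n_disengagement_per_condition = 16L,
                      latency_mean_ms = 420, latency_sd_ms = 120,
                      p_no_shift = 0.3, fixation_noise_deg = 0.8,
                      gap_prob = 0, gap_dur_ms = c(220, 300),
                      gap_start_ms = 400,
                      lateral_onset_ms = 1000, trial_len_ms = 2200,
                      sample_rate_hz = 300,
                      central_aoi = aoi(0, 0, 5, 5),
                      lateral_aoi = aoi(19, 0, 10.9, 9.5),
                      seed = 1L) {
  .assert(p_no_shift >= 0 && p_no_shift <= 1, "p_no_shift must be in [0,1]")
  .assert(gap_prob >= 0 && gap_prob <= 1, "gap_prob must be in [0,1]")
  structure(list(
    n_orienting_trials = as.integer(n_orienting_trials),
    n_disengagement_per_condition =
      as.integer(n_disengagement_per_condition),
    latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
    p_no_shift = p_no_shift, fixation_noise_deg = fixation_noise_deg,
    gap_prob = gap_prob, gap_dur_ms = rep_len(gap_dur_ms, 2L),
    gap_start_ms = gap_start_ms,
    lateral_onset_ms = lateral_onset_ms, trial_len_ms = trial_len_ms,
    sample_rate_hz = sample_rate_hz,
    central_aoi = central_aoi, lateral_aoi = lateral_aoi,
    seed = as.integer(seed)
  ), class = "gaze_spec")
}

# truncated-normal latency draw inside the scoring window (one sample margin)
draw_latency <- function(n, spec, cfg) {
  step <- 1000 / spec$sample_rate_hz
  lo <- cfg$window_start_ms + step
  hi <- cfg$window_end_ms - step
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      l <- stats::rnorm(1, spec$latency_mean_ms, spec$latency_sd_ms)
      if (l >= lo && l <= hi) break
    }
    out[i] <- l
  }
  out
}

#' Generate a synthetic gaze session
#'
#' @param spec A \code{\link{gaze_spec}}.
#' @param cfg A \code{\link{scoring_config}} (latency truncation window).
#' @param participant_id Prefix for trial ids.
#' @return A list with \code{gaze} and \code{events} data.frames matching
#'   the \code{\link{read_gaze_file}} contract, and \code{truth}: one row
#'   per trial with \code{trial_id}, \code{task}, \code{condition},
#'   \code{latency_ms} (NA for no-shift trials), \code{gap_injected}.
#' @export
synth_gaze <- function(spec = gaze_spec(), cfg = scoring_config(),
                       participant_id = "P1") {
  with_seed(spec$seed, {
    step <- 1000 / spec$sample_rate_hz
    times <- seq(0, spec$trial_len_ms, by = step)
    conds <- c(rep("target", spec$n_orienting_trials),
               rep(c("happy", "fearful", "nonface"),
                   each = spec$n_disengagement_per_condition))
    tasks <- c(rep("orienting", spec$n_orienting_trials),
               rep("disengagement",
                   3L * spec$n_disengagement_per_condition))
    n_trials <- length(tasks)

    gaze_rows <- list(); events_rows <- list(); truth_rows <- list()
    for (i in seq_len(n_trials)) {
      id <- sprintf("%s_T%03d", participant_id, i)
      no_shift <- tasks[i] == "disengagement" &&
        stats::runif(1) < spec$p_no_shift
      lat <- if (no_shift) NA_real_ else draw_latency(1, spec, cfg)
      shift_t <- spec$lateral_onset_ms + lat

      cx <- spec$central_aoi$center_x; cy <- spec$central_aoi$center_y
      lx <- spec$lateral_aoi$center_x; ly <- spec$lateral_aoi$center_y
      at_lateral <- !no_shift & times >= shift_t
      x <- ifelse(at_lateral, lx, cx) +
        stats::rnorm(length(times), 0, spec$fixation_noise_deg)
      y <- ifelse(at_lateral, ly, cy) +
        stats::rnorm(length(times), 0, spec$fixation_noise_deg)
      valid <- rep(TRUE, length(times))

      gap <- stats::runif(1) < spec$gap_prob
      if (gap) {
        dur <- runif_range(1, spec$gap_dur_ms)
        valid[times > spec$gap_start_ms &
                times < spec$gap_start_ms + dur] <- FALSE
      }

      gaze_rows[[i]] <- data.frame(
        trial_id = id, task = tasks[i], condition = conds[i],
        time_ms = times, x = x, y = y, valid = valid)
      events_rows[[i]] <- data.frame(
        trial_id = id, participant_id = participant_id,
        lateral_onset_ms = spec$lateral_onset_ms,
        central_x = cx, central_y = cy,
        central_w = spec$central_aoi$width,
        central_h = spec$central_aoi$height,
        lateral_x = lx, lateral_y = ly,
        lateral_w = spec$lateral_aoi$width,
        lateral_h = spec$lateral_aoi$height)
      truth_rows[[i]] <- data.frame(
        trial_id = id, task = tasks[i], condition = conds[i],
        latency_ms = lat, gap_injected = gap)
    }
    list(gaze = do.call(rbind, gaze_rows),
         events = do.call(rbind, events_rows),
         truth = do.call(rbind, truth_rows))
  })
}
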