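# Shared fixtures, built in code.

FS <- 48000L

# wrap raw samples as an audio_recording without touching the filesystem
make_recording <- function(samples, fs = FS, bout_start = FALSE) {
  structure(list(samples = samples, sample_rate_hz = as.integer(fs),
                 n_channels = 1L, source_path = "<fixture>",
                 bout_start_captured = bout_start),
            class = "audio_recording")
}

# harmonic signal following an instantaneous F0 contour (Hz per sample)
harmonic_signal <- function(f0_inst, fs = FS, n_harmonics = 6L,
                            amplitude = 0.5) {
  phase <- 2 * pi * cumsum(f0_inst) / fs
  x <- numeric(length(f0_inst))
  for (k in seq_len(n_harmonics)) x <- x + sin(k * phase) / k
  amplitude * x / max(abs(x))
}

# a synthetic phase_track with prescribed duration and per-frame retention,
# for exercising the selection/aggregation arithmetic without audio
make_track <- function(duration_s, f0_mean = 450, f0_sd = 10,
                       n_frames = 20L, inharmonic_fraction = 0,
                       start_s = 0) {
  n_bad <- round(inharmonic_fraction * n_frames)
  ap <- c(rep(0.9, n_bad), rep(0.05, n_frames - n_bad))
  f0 <- ifelse(ap > 0.3, NA_real_,
               f0_mean + f0_sd * scale(seq_len(n_frames))[, 1])
  retained <- !is.na(f0)
  kept <- f0[retained]
  structure(list(
    start_s = start_s, end_s = start_s + duration_s,
    duration_s = duration_s,
    frames = data.frame(time_s = seq_len(n_frames) * 0.0125, f0_hz = f0,
                        aperiodicity = ap, retained = retained),
    n_frames = n_frames, n_retained = sum(retained),
    inharmonic_fraction = mean(ap > 0.3),
    phase_f0_mean_hz = if (any(retained)) mean(kept) else NA_real_,
    phase_f0_sd_hz = if (sum(retained) > 1) sd(kept) else NA_real_
  ), class = "phase_track")
}

# noiseless gaze trial: central fixation, step to the lateral AOI at
# `latency_ms` after onset (NA = no shift), 300-Hz grid
make_trial <- function(latency_ms = 400, task = "disengagement",
                       condition = "happy", onset_ms = 1000,
                       trial_len_ms = 2200, rate_hz = 300,
                       central = aoi(0, 0, 5, 5),
                       lateral = aoi(19, 0, 10.9, 9.5),
                       trial_id = "T1") {
  times <- seq(0, trial_len_ms, by = 1000 / rate_hz)
  shifted <- if (is.na(latency_ms)) rep(FALSE, length(times)) else
    times >= onset_ms + latency_ms
  list(trial_id = trial_id, task = task, condition = condition,
       central_aoi = central, lateral_aoi = lateral,
       lateral_onset_ms = onset_ms,
       samples = data.frame(
         time_ms = times,
         x = ifelse(shifted, lateral$center_x, central$center_x),
         y = ifelse(shifted, lateral$center_y, central$center_y),
         valid = TRUE))
}

# mark samples in (t0, t1) invalid
inject_gap <- function(trial, t0, t1) {
  sel <- trial$samples$time_ms > t0 & trial$samples$time_ms < t1
  trial$samples$valid[sel] <- FALSE
  trial
}
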