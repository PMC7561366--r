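# Phase-level pitch tracking, phase selection, and the participant-level
# F0 / F0var features.

#' Pitch-track one expiratory phase
#'
#' Frames the phase, estimates per-frame F0 and aperiodicity, discards frames
#' whose aperiodicity exceeds the configured threshold, and computes the
#' phase-level F0 mean and sample SD over the surviving frames.
#'
#' @param segment One row of the segment table (must be expiratory).
#' @param rec The \code{audio_recording} the segment indexes into.
#' @param cfg A \code{\link{yin_config}}.
#' @return An object of class \code{phase_track}: a list with
#'   \code{start_s}, \code{end_s}, \code{duration_s}, \code{frames} (per-frame
#'   data.frame with \code{time_s}, \code{f0_hz}, \code{aperiodicity},
#'   \code{retained}), \code{n_frames}, \code{n_retained},
#'   \code{inharmonic_fraction}, \code{phase_f0_mean_hz},
#'   \code{phase_f0_sd_hz} (NA when no frame survives).
#' @export
track_phase <- function(segment, rec, cfg = yin_config()) {
  .assert(identical(as.character(segment$label), "expiratory"),
          "track_phase expects an expiratory segment, got %s", segment$label)
  i0 <- max(1L, as.integer(floor(segment$start_s * rec$sample_rate_hz)) + 1L)
  i1 <- min(length(rec$samples),
            as.integer(ceiling(segment$end_s * rec$sample_rate_hz)))
  framed <- frame_signal(rec$samples[i0:i1], rec$sample_rate_hz, cfg)
  track <- pitch_track_frames(framed, rec$sample_rate_hz, cfg)
  track$time_s <- track$time_s + (i0 - 1L) / rec$sample_rate_hz
  track$retained <- !is.na(track$f0_hz)
  n_frames <- nrow(track)
  n_ret <- sum(track$retained)
  f0s <- track$f0_hz[track$retained]
  structure(list(
    start_s = segment$start_s, end_s = segment$end_s,
    duration_s = segment$end_s - segment$start_s,
    frames = track, n_frames = n_frames, n_retained = n_ret,
    inharmonic_fraction = if (n_frames > 0L)
      mean(track$aperiodicity > cfg$aperiodicity_threshold) else 1,
    phase_f0_mean_hz = if (n_ret > 0L) mean(f0s) else NA_real_,
    phase_f0_sd_hz = if (n_ret > 1L) stats::sd(f0s) else
      if (n_ret == 1L) 0 else NA_real_
  ), class = "phase_track")
}

#' Select the expiratory phases entering the participant features
#'
#' Applies the phase filters in temporal order: phases must be strictly
#' longer than \code{min_phase_dur_ms} and have an inharmonic-frame fraction
#' of at most \code{max_inharmonic_fraction}; the first \code{max_phases}
#' survivors are kept. A recording is usable only when at least
#' \code{min_phases} phases survive.
#'
#' @param tracks List of \code{phase_track}s in temporal order.
#' @param cfg A \code{\link{yin_config}}.
#' @return A list with \code{tracks} (the kept phases), \code{n_available}
#'   (survivor count before the cap), and \code{usable}.
#' @export
select_phases <- function(tracks, cfg = yin_config()) {
  keep <- vapply(tracks, function(tr) {
    tr$duration_s * 1000 > cfg$min_phase_dur_ms &&
      tr$inharmonic_fraction <= cfg$max_inharmonic_fraction &&
      tr$n_retained > 0L
  }, logical(1))
  survivors <- tracks[keep]
  n_avail <- length(survivors)
  selected <- survivors[seq_len(min(n_avail, cfg$max_phases))]
  list(tracks = selected, n_available = n_avail,
       usable = length(selected) >= cfg$min_phases)
}

#' Aggregate selected phases into the participant-level cry features
#'
#' F0 is the arithmetic mean of the per-phase F0 means; F0var is the
#' arithmetic mean of the per-phase F0 standard deviations. When fewer than
#' the maximum number of phases are available, the mean over the available
#' phases is used.
#'
#' @param selected Result of \code{\link{select_phases}}, or a plain list of
#'   \code{phase_track}s.
#' @param cfg A \code{\link{yin_config}} (bounds on the phase count).
#' @return An object of class \code{cry_features}: list with \code{f0_hz},
#'   \code{f0var_hz}, \code{n_phases_used}, \code{per_phase_means},
#'   \code{per_phase_sds}, \code{usable}.
#' @export
compute_features <- function(selected, cfg = yin_config()) {
  tracks <- if (is.list(selected) && !is.null(selected$tracks))
    selected$tracks else selected
  n <- length(tracks)
  .assert(n >= cfg$min_phases && n <= cfg$max_phases,
          "compute_features needs %d..%d phases, got %d",
          cfg$min_phases, cfg$max_phases, n)
  means <- vapply(tracks, `[[`, numeric(1), "phase_f0_mean_hz")
  sds <- vapply(tracks, `[[`, numeric(1), "phase_f0_sd_hz")
  structure(list(
    f0_hz = mean(means), f0var_hz = mean(sds), n_phases_used = n,
    per_phase_means = means, per_phase_sds = sds, usable = TRUE
  ), class = "cry_features")
}

unusable_features <- function(n_available) {
  structure(list(
    f0_hz = NA_real_, f0var_hz = NA_real_,
    n_phases_used = as.integer(n_available),
    per_phase_means = numeric(0), per_phase_sds = numeric(0), usable = FALSE
  ), class = "cry_features")
}

#' @export
print.cry_features <- function(x, ...) {
  if (x$usable) {
    cat(sprintf("<cry_features> F0 %.1f Hz, F0var %.1f Hz (%d phases)\n",
                x$f0_hz, x$f0var_hz, x$n_phases_used))
  } else {
    cat(sprintf("<cry_features> unusable (%d scorable phases, need >= 3)\n",
                x$n_phases_used))
  }
  invisible(x)
}

#' Full acoustic pipeline for one recording
#'
#' Segments the recording, pitch-tracks every expiratory phase, applies the
#' phase filters, and aggregates the participant-level features.
#'
#' @param rec An \code{audio_recording}.
#' @param cfg A \code{\link{yin_config}}.
#' @param seg_cfg A \code{\link{seg_config}}.
#' @return A list with \code{features} (\code{cry_features}),
#'   \code{segments} (segment table), \code{tracks} (all expiratory
#'   \code{phase_track}s), and \code{diagnostics} (per-phase data.frame:
#'   \code{start_s}, \code{end_s}, \code{n_frames}, \code{n_retained},
#'   \code{inharmonic_fraction}, \code{phase_mean}, \code{phase_sd},
#'   \code{selected}).
#' @export
cry_features <- function(rec, cfg = yin_config(), seg_cfg = seg_config()) {
  segs <- segment_recording(rec, cfg, seg_cfg)
  exp_segs <- segs[segs$label == "expiratory", , drop = FALSE]
  tracks <- lapply(seq_len(nrow(exp_segs)), function(i)
    track_phase(exp_segs[i, ], rec, cfg))
  sel <- select_phases(tracks, cfg)
  feats <- if (sel$usable) compute_features(sel, cfg) else
    unusable_features(length(sel$tracks))
  sel_ids <- vapply(sel$tracks, `[[`, numeric(1), "start_s")
  diag <- do.call(rbind, lapply(tracks, function(tr) data.frame(
    start_s = tr$start_s, end_s = tr$end_s, n_frames = tr$n_frames,
    n_retained = tr$n_retained,
    inharmonic_fraction = tr$inharmonic_fraction,
    phase_mean = tr$phase_f0_mean_hz, phase_sd = tr$phase_f0_sd_hz,
    selected = tr$start_s %in% sel_ids
  )))
  list(features = feats, segments = segs, tracks = tracks,
       diagnostics = diag %||% data.frame())
}

#' Batch feature extraction over WAV files
#'
#' @param paths Character vector of WAV paths.
#' @param bout_start_captured Logical, recycled over \code{paths}.
#' @param cfg,seg_cfg Analysis configurations.
#' @return A list with \code{features} (one row per recording:
#'   \code{recording_id}, \code{f0_hz}, \code{f0var_hz},
#'   \code{n_phases_used}, \code{usable}, \code{bout_start_captured}) and
#'   \code{diagnostics} (per-phase rows tagged by \code{recording_id}).
#' @export
extract_cry_features <- function(paths, bout_start_captured = FALSE,
                                 cfg = yin_config(),
                                 seg_cfg = seg_config()) {
  bout <- rep_len(bout_start_captured, length(paths))
  feats <- list(); diags <- list()
  for (i in seq_along(paths)) {
    id <- tools::file_path_sans_ext(basename(paths[i]))
    res <- cry_features(load_recording(paths[i], bout[i]), cfg, seg_cfg)
    f <- res$features
    feats[[i]] <- data.frame(
      recording_id = id, f0_hz = f$f0_hz, f0var_hz = f$f0var_hz,
      n_phases_used = f$n_phases_used, usable = f$usable,
      bout_start_captured = bout[i]
    )
    if (nrow(res$diagnostics) > 0L) {
      diags[[i]] <- cbind(recording_id = id, res$diagnostics)
    }
  }
  list(features = do.call(rbind, feats) %||% data.frame(),
       diagnostics = do.call(rbind, diags) %||% data.frame())
}
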