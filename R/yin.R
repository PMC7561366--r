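# Frame-based F0 estimation with the YIN cumulative-mean-normalized
# difference function, restricted to the cry F0 band.

#' Analysis configuration for cry pitch extraction
#'
#' Bundles the framing, search-band, and filtering parameters used throughout
#' the acoustic arm. Defaults are the neonatal-cry analysis settings: 25-ms
#' frames with a 12.5-ms hop (50\% overlap), an F0 search band of 200-700 Hz,
#' an aperiodicity cut of 0.3, a 500-ms minimum expiratory-phase duration, at
#' most 70\% inharmonic frames per phase, and aggregation over the first five
#' (minimum three) surviving expiratory phases.
#'
#' @param frame_len_ms Analysis frame length in milliseconds.
#' @param hop_ms Hop between successive frame starts in milliseconds.
#' @param f0_min_hz Lower edge of the F0 search band (Hz).
#' @param f0_max_hz Upper edge of the F0 search band (Hz).
#' @param aperiodicity_threshold Frames whose aperiodicity exceeds this value
#'   are treated as inharmonic and their F0 estimates discarded.
#' @param min_phase_dur_ms Expiratory phases must be strictly longer than this
#'   to enter the analysis.
#' @param max_inharmonic_fraction Phases with a larger fraction of inharmonic
#'   frames are excluded.
#' @param max_phases,min_phases Number of expiratory phases aggregated into
#'   the participant-level features: the first \code{max_phases} survivors,
#'   requiring at least \code{min_phases} for a usable recording.
#' @return An object of class \code{yin_config}.
#' @export
yin_config <- function(frame_len_ms = 25, hop_ms = 12.5,
                       f0_min_hz = 200, f0_max_hz = 700,
                       aperiodicity_threshold = 0.3,
                       min_phase_dur_ms = 500,
                       max_inharmonic_fraction = 0.7,
                       max_phases = 5L, min_phases = 3L) {
  .assert(f0_min_hz > 0 && f0_min_hz < f0_max_hz,
          "need 0 < f0_min_hz < f0_max_hz")
  .assert(hop_ms > 0 && hop_ms <= frame_len_ms,
          "need 0 < hop_ms <= frame_len_ms")
  .assert(aperiodicity_threshold > 0 && aperiodicity_threshold < 1,
          "aperiodicity_threshold must be in (0,1)")
  .assert(max_inharmonic_fraction > 0 && max_inharmonic_fraction < 1,
          "max_inharmonic_fraction must be in (0,1)")
  .assert(min_phases >= 1L && min_phases <= max_phases,
          "need 1 <= min_phases <= max_phases")
  structure(list(
    frame_len_ms = frame_len_ms, hop_ms = hop_ms,
    f0_min_hz = f0_min_hz, f0_max_hz = f0_max_hz,
    aperiodicity_threshold = aperiodicity_threshold,
    min_phase_dur_ms = min_phase_dur_ms,
    max_inharmonic_fraction = max_inharmonic_fraction,
    max_phases = as.integer(max_phases), min_phases = as.integer(min_phases)
  ), class = "yin_config")
}

#' Load a cry recording
#'
#' Reads a WAV file, mixes stereo to mono by channel mean, and returns an
#' \code{audio_recording} with samples in \code{[-1, 1]}.
#'
#' @param path Path to the WAV file.
#' @param bout_start_captured Whether the recording starts at the beginning of
#'   the cry bout (carried through to the feature table).
#' @return An object of class \code{audio_recording} with fields
#'   \code{samples}, \code{sample_rate_hz}, \code{n_channels},
#'   \code{source_path}, \code{bout_start_captured}.
#' @export
load_recording <- function(path, bout_start_captured = FALSE) {
  w <- read_wav(path)
  .assert(nrow(w$samples) > 0L, "empty audio in %s", path)
  mono <- if (w$n_channels == 1L) w$samples[, 1L] else rowMeans(w$samples)
  .assert(w$sample_rate_hz / 2 > 0, "invalid sample rate in %s", path)
  structure(list(
    samples = mono, sample_rate_hz = w$sample_rate_hz,
    n_channels = w$n_channels, source_path = path,
    bout_start_captured = isTRUE(bout_start_captured)
  ), class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.2f s @ %d Hz (%d channel%s) %s\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz,
              x$n_channels, if (x$n_channels > 1L) "s" else "",
              x$source_path))
  invisible(x)
}

#' Split a signal into overlapping analysis frames
#'
#' Frames are \code{round(frame_len_ms * rate / 1000)} samples long, with
#' successive starts \code{round(hop_ms * rate / 1000)} samples apart. A
#' trailing partial frame is discarded.
#'
#' @param samples Numeric amplitude vector.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param cfg A \code{\link{yin_config}}.
#' @return A list with \code{frames} (matrix, one column per frame),
#'   \code{centers_s} (frame-center times in seconds), \code{frame_len},
#'   \code{hop} (both in samples). Empty when the signal is shorter than one
#'   frame.
#' @export
frame_signal <- function(samples, sample_rate_hz, cfg = yin_config()) {
  frame_len <- as.integer(round(cfg$frame_len_ms * sample_rate_hz / 1000))
  hop <- as.integer(round(cfg$hop_ms * sample_rate_hz / 1000))
  n <- length(samples)
  if (n < frame_len) {
    return(list(frames = matrix(numeric(0), nrow = frame_len, ncol = 0),
                centers_s = numeric(0), frame_len = frame_len, hop = hop))
  }
  n_frames <- (n - frame_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  idx <- outer(seq_len(frame_len) - 1L, starts, `+`)
  list(frames = matrix(samples[idx], nrow = frame_len),
       centers_s = (starts - 1L + frame_len / 2) / sample_rate_hz,
       frame_len = frame_len, hop = hop)
}

# Cumulative-mean-normalized difference function of one frame, evaluated for
# lags 1..tau_max with a fixed integration window of length(x) - tau_max.
# d'(tau) = d(tau) * tau / sum_{j<=tau} d(j); d'(0) is defined as 1.
yin_cmnd <- function(x, tau_max) {
  n <- length(x)
  w <- n - tau_max
  .assert(w >= tau_max, "frame too short for the requested lag range")
  head_x <- x[seq_len(w)]
  d <- vapply(seq_len(tau_max), function(tau) {
    dx <- head_x - x[tau + seq_len(w)]
    sum(dx * dx)
  }, numeric(1))
  cs <- cumsum(d)
  dp <- ifelse(cs > 0, d * seq_len(tau_max) / cs, 1)
  dp
}

# Parabolic refinement of a local minimum at integer lag i of y; returns the
# refined abscissa and ordinate, clamped to [i-1, i+1].
parabolic_min <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(c(lag = i, value = y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  den <- a - 2 * b + c
  if (den <= 0) return(c(lag = i, value = b))
  delta <- 0.5 * (a - c) / den
  delta <- max(min(delta, 1), -1)
  c(lag = i + delta, value = b - 0.25 * (a - c) * delta)
}

#' Estimate F0 and aperiodicity for one frame
#'
#' Computes the YIN difference function and its cumulative-mean-normalized
#' form, picks the first lag dip below the absolute threshold within the F0
#' search band (falling back to the in-band global minimum), refines the lag
#' by parabolic interpolation, and reports \code{f0_hz = rate / lag} together
#' with the normalized-difference value at that lag as the aperiodicity. The
#' F0 estimate is absent (\code{NA}) when the aperiodicity exceeds the
#' configured threshold; a constant frame reports infinite aperiodicity.
#'
#' @param frame Numeric vector, one analysis frame.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param cfg A \code{\link{yin_config}}.
#' @param time_s Optional frame-center time carried into the result.
#' @return A one-row data.frame with \code{time_s}, \code{f0_hz} (NA when
#'   rejected), \code{aperiodicity}.
#' @export
estimate_pitch_frame <- function(frame, sample_rate_hz, cfg = yin_config(),
                                 time_s = NA_real_) {
  tau_min <- as.integer(ceiling(sample_rate_hz / cfg$f0_max_hz))
  tau_max <- as.integer(floor(sample_rate_hz / cfg$f0_min_hz))
  .assert(tau_min >= 2L && tau_min < tau_max,
          "F0 band maps to an empty lag range at %d Hz", sample_rate_hz)
  if (stats::var(frame) == 0) {
    return(data.frame(time_s = time_s, f0_hz = NA_real_,
                      aperiodicity = Inf))
  }
  dp <- yin_cmnd(frame, tau_max)
  band <- tau_min:tau_max
  thr <- cfg$aperiodicity_threshold

  below <- band[dp[band] < thr]
  tau <- if (length(below) > 0L) {
    # first dip: descend to the local minimum of the first below-threshold run
    t0 <- below[1L]
    while (t0 < tau_max && dp[t0 + 1L] < dp[t0]) t0 <- t0 + 1L
    t0
  } else {
    band[which.min(dp[band])]
  }
  ref <- parabolic_min(dp, tau)
  ap <- max(ref[["value"]], 0)
  f0 <- sample_rate_hz / ref[["lag"]]
  f0 <- min(max(f0, cfg$f0_min_hz), cfg$f0_max_hz)
  data.frame(time_s = time_s,
             f0_hz = if (ap > thr) NA_real_ else f0,
             aperiodicity = ap)
}

# Vectorized per-frame pitch track for a framed signal (internal workhorse
# shared by track_phase and the segmenter's harmonicity feature).
pitch_track_frames <- function(framed, sample_rate_hz, cfg) {
  nf <- ncol(framed$frames)
  if (nf == 0L) {
    return(data.frame(time_s = numeric(0), f0_hz = numeric(0),
                      aperiodicity = numeric(0)))
  }
  rows <- lapply(seq_len(nf), function(i) {
    estimate_pitch_frame(framed$frames[, i], sample_rate_hz, cfg,
                         time_s = framed$centers_s[i])
  })
  do.call(rbind, rows)
}
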