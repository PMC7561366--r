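# Frame-level cry segmentation.
#
# Partitions the active (non-silent) parts of a recording into expiratory,
# inspiratory, and residual regions. Each analysis frame is described by
# short-time energy, harmonicity (the minimum of the cumulative-mean-
# normalized difference function inside the F0 search band), and spectral
# slope; frame labels are mode-smoothed and merged into minimum-duration
# segments. Expiratory cries are harmonic, inspiratory sounds (whistly
# inhalations) are noise-like with high-frequency emphasis, and everything
# else that is audible but neither of those is residual.

#' Segmentation configuration
#'
#' @param energy_floor_db Absolute silence floor (dBFS); frames below it are
#'   never active.
#' @param energy_margin_db Frames must exceed the recording's adaptive noise
#'   floor (5th percentile of frame energy) by this margin to be active.
#' @param voiced_ap_max Frames with a normalized-difference minimum at or
#'   below this value are considered harmonic (expiratory).
#' @param slope_insp_db_per_khz Non-harmonic active frames whose spectral
#'   slope exceeds this value (high-frequency emphasis, in dB/kHz) are
#'   labeled inspiratory; otherwise residual.
#' @param smooth_frames Width (frames) of the label mode filter.
#' @param min_seg_ms Segments shorter than this are discarded.
#' @return An object of class \code{seg_config}.
#' @export
seg_config <- function(energy_floor_db = -65, energy_margin_db = 8,
                       voiced_ap_max = 0.45, slope_insp_db_per_khz = 1,
                       smooth_frames = 5L, min_seg_ms = 100) {
  structure(list(energy_floor_db = energy_floor_db,
                 energy_margin_db = energy_margin_db,
                 voiced_ap_max = voiced_ap_max,
                 slope_insp_db_per_khz = slope_insp_db_per_khz,
                 smooth_frames = as.integer(smooth_frames),
                 min_seg_ms = min_seg_ms), class = "seg_config")
}

# Spectral slope in dB/kHz: OLS fit of the periodogram (dB) against frequency
# over 300 Hz .. min(10 kHz, Nyquist).
spectral_slope <- function(frame, sample_rate_hz) {
  n <- length(frame)
  spec <- abs(stats::fft(frame * signal::hanning(n)))^2
  freqs <- (seq_len(n) - 1L) * sample_rate_hz / n
  keep <- freqs >= 300 & freqs <= min(10000, sample_rate_hz / 2)
  p <- 10 * log10(spec[keep] + 1e-20)
  f_khz <- freqs[keep] / 1000
  stats::cov(f_khz, p) / stats::var(f_khz)
}

# Sliding-window mode filter for integer label codes.
mode_smooth <- function(codes, width) {
  if (width <= 1L || length(codes) < width) return(codes)
  half <- width %/% 2L
  n <- length(codes)
  out <- codes
  for (i in seq_len(n)) {
    w <- codes[max(1L, i - half):min(n, i + half)]
    tab <- tabulate(w + 1L)
    out[i] <- which.max(tab) - 1L
  }
  out
}

#' Segment a cry recording into expiratory / inspiratory / residual regions
#'
#' @param rec An \code{audio_recording} (see \code{\link{load_recording}}).
#' @param cfg A \code{\link{yin_config}} providing framing and the F0 band.
#' @param seg_cfg A \code{\link{seg_config}}.
#' @return A data.frame of segments with columns \code{start_s}, \code{end_s},
#'   \code{label} (one of \code{"expiratory"}, \code{"inspiratory"},
#'   \code{"residual"}), sorted and non-overlapping. Empty for silence.
#' @export
segment_recording <- function(rec, cfg = yin_config(),
                              seg_cfg = seg_config()) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0))
  framed <- frame_signal(rec$samples, rec$sample_rate_hz, cfg)
  nf <- ncol(framed$frames)
  if (nf == 0L) return(empty)

  energy_db <- 10 * log10(colMeans(framed$frames^2) + 1e-30)
  floor_db <- stats::quantile(energy_db, 0.05, names = FALSE)
  active <- energy_db > max(seg_cfg$energy_floor_db,
                            floor_db + seg_cfg$energy_margin_db)
  if (!any(active)) return(empty)

  tau_min <- as.integer(ceiling(rec$sample_rate_hz / cfg$f0_max_hz))
  tau_max <- as.integer(floor(rec$sample_rate_hz / cfg$f0_min_hz))
  codes <- integer(nf)                    # 0 none, 1 exp, 2 insp, 3 resid
  for (i in which(active)) {
    x <- framed$frames[, i]
    if (stats::var(x) == 0) next
    ap <- min(yin_cmnd(x, tau_max)[tau_min:tau_max])
    if (ap <= seg_cfg$voiced_ap_max) {
      codes[i] <- 1L
    } else {
      sl <- spectral_slope(x, rec$sample_rate_hz)
      codes[i] <- if (sl > seg_cfg$slope_insp_db_per_khz) 2L else 3L
    }
  }
  codes <- mode_smooth(codes, seg_cfg$smooth_frames)

  # each frame owns the hop-length tile around its center, so consecutive
  # runs yield non-overlapping segments
  half_hop_s <- framed$hop / (2 * rec$sample_rate_hz)
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  segs <- data.frame(
    start_s = framed$centers_s[begins] - half_hop_s,
    end_s = framed$centers_s[ends] + half_hop_s,
    label = c("none", "expiratory", "inspiratory", "residual")[r$values + 1L]
  )
  segs <- segs[segs$label != "none", , drop = FALSE]
  segs <- segs[(segs$end_s - segs$start_s) * 1000 >= seg_cfg$min_seg_ms, ,
               drop = FALSE]
  rownames(segs) <- NULL
  segs
}
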