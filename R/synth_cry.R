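# Synthetic cry-bout generator with exact ground truth.
#
# A cry bout is a sequence of expiratory phases (harmonic additive source
# with a slowly drifting F0 contour), separated by pauses and optionally
# followed by short inspiratory noise bursts (high-pass filtered noise).
# The within-phase F0 contour is base + A sin(2 pi f t + phi) with
# A = sqrt(2) * target SD, so the contour's long-run SD equals the target
# exactly; truth statistics are evaluated on the analysis frame grid.

#' Specification of a synthetic cry bout
#'
#' @param n_expiratory Number of expiratory phases.
#' @param phase_dur_s Length-2 range (s) from which phase durations are drawn
#'   uniformly; a single value fixes the duration.
#' @param pause_dur_s Range (s) of silent pauses between phases.
#' @param f0_base_mean_hz,f0_base_sd_hz Normal distribution of per-phase base
#'   F0 (Hz); draws are clipped to the analysis band.
#' @param f0_within_sd_hz Target within-phase F0 SD (Hz), realized as a slow
#'   sinusoidal drift of matching amplitude.
#' @param drift_hz Frequency of the within-phase F0 drift (Hz).
#' @param jitter_hz SD of additional per-frame F0 jitter (Hz); 0 keeps the
#'   within-phase SD analytic.
#' @param n_harmonics Number of harmonics in the additive source (amplitudes
#'   decay as 1/k).
#' @param snr_db Signal-to-noise ratio of added white noise (dB);
#'   \code{Inf} for a noise-free bout.
#' @param include_inspiratory Add a short high-pass noise burst (an
#'   inhalation) after each expiratory phase.
#' @param amplitude Peak amplitude of the expiratory source.
#' @param sample_rate_hz Sampling rate.
#' @param seed RNG seed; the generator is seed-deterministic.
#' @return An object of class \code{cry_spec}.
#' @export
cry_spec <- function(n_expiratory = 5L, phase_dur_s = c(0.7, 1.2),
                     pause_dur_s = c(0.25, 0.45),
                     f0_base_mean_hz = 463.45, f0_base_sd_hz = 30,
                     f0_within_sd_hz = 65.18, drift_hz = 2,
                     jitter_hz = 0, n_harmonics = 8L, snr_db = 30,
                     include_inspiratory = FALSE, amplitude = 0.5,
                     sample_rate_hz = 48000L, seed = 1L) {
  .assert(all(phase_dur_s > 0) && all(pause_dur_s > 0), "durations must be positive")
  structure(list(
    n_expiratory = as.integer(n_expiratory),
    phase_dur_s = rep_len(phase_dur_s, 2L),
    pause_dur_s = rep_len(pause_dur_s, 2L),
    f0_base_mean_hz = f0_base_mean_hz, f0_base_sd_hz = f0_base_sd_hz,
    f0_within_sd_hz = f0_within_sd_hz, drift_hz = drift_hz,
    jitter_hz = jitter_hz, n_harmonics = as.integer(n_harmonics),
    snr_db = snr_db, include_inspiratory = isTRUE(include_inspiratory),
    amplitude = amplitude, sample_rate_hz = as.integer(sample_rate_hz),
    seed = as.integer(seed)
  ), class = "cry_spec")
}

runif_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    stats::runif(n, range[1], range[2])
}

# Harmonic source following the F0 contour f0_of_t (Hz at sample times),
# with 1/k harmonic amplitude decay and raised-cosine edge ramps.
harmonic_phase <- function(f0_inst, sample_rate_hz, n_harmonics, amplitude,
                           ramp_s = 0.025) {
  n <- length(f0_inst)
  phase <- 2 * pi * cumsum(f0_inst) / sample_rate_hz
  x <- numeric(n)
  for (k in seq_len(n_harmonics)) x <- x + sin(k * phase) / k
  x <- x / max(abs(x))
  nr <- min(as.integer(ramp_s * sample_rate_hz), n %/% 2L)
  if (nr > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(ramp)
  }
  amplitude * x
}

#' Generate a synthetic cry bout
#'
#' @param spec A \code{\link{cry_spec}}.
#' @param cfg A \code{\link{yin_config}}; its F0 band clips base-F0 draws and
#'   its frame grid defines where truth statistics are evaluated.
#' @return A list with \code{recording} (an \code{audio_recording}),
#'   \code{truth}: list with \code{segments} (data.frame \code{start_s},
#'   \code{end_s}, \code{label}), \code{phases} (data.frame \code{phase},
#'   \code{start_s}, \code{end_s}, \code{f0_base_hz}, \code{f0_mean_hz},
#'   \code{f0_sd_hz} — contour statistics on the frame grid), and
#'   \code{spec}.
#' @export
synth_cry <- function(spec = cry_spec(), cfg = yin_config()) {
  .assert(spec$f0_base_mean_hz > cfg$f0_min_hz &&
            spec$f0_base_mean_hz < cfg$f0_max_hz,
          "base F0 outside the analysis band %g-%g Hz",
          cfg$f0_min_hz, cfg$f0_max_hz)
  fs <- spec$sample_rate_hz
  with_seed(spec$seed, {
    n_ph <- spec$n_expiratory
    durs <- runif_range(n_ph, spec$phase_dur_s)
    pauses <- runif_range(n_ph + 1L, spec$pause_dur_s)
    bases <- if (n_ph > 0L) pmin(pmax(
      stats::rnorm(n_ph, spec$f0_base_mean_hz, spec$f0_base_sd_hz),
      cfg$f0_min_hz + 2 * spec$f0_within_sd_hz),
      cfg$f0_max_hz - 2 * spec$f0_within_sd_hz) else numeric(0)
    phis <- stats::runif(n_ph, 0, 2 * pi)

    pieces <- list(numeric(as.integer(pauses[1L] * fs)))
    seg_rows <- list()
    phase_rows <- list()
    t_cursor <- pauses[1L]
    amp_sin <- sqrt(2) * spec$f0_within_sd_hz
    frame_len_s <- cfg$frame_len_ms / 1000
    hop_s <- cfg$hop_ms / 1000

    for (i in seq_len(n_ph)) {
      n <- as.integer(durs[i] * fs)
      tt <- (seq_len(n) - 1L) / fs
      f0_inst <- bases[i] +
        amp_sin * sin(2 * pi * spec$drift_hz * tt + phis[i])
      if (spec$jitter_hz > 0) {
        # jitter held constant within each analysis frame hop
        n_hops <- ceiling(n / (hop_s * fs))
        j <- stats::rnorm(n_hops, 0, spec$jitter_hz)
        f0_inst <- f0_inst + rep(j, each = as.integer(hop_s * fs))[seq_len(n)]
      }
      pieces[[length(pieces) + 1L]] <-
        harmonic_phase(f0_inst, fs, spec$n_harmonics, spec$amplitude)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        start_s = t_cursor, end_s = t_cursor + durs[i], label = "expiratory")

      # truth F0 statistics at the analysis frame centers inside the phase
      centers <- seq(frame_len_s / 2, durs[i] - frame_len_s / 2, by = hop_s)
      f0_at <- bases[i] +
        amp_sin * sin(2 * pi * spec$drift_hz * centers + phis[i])
      phase_rows[[length(phase_rows) + 1L]] <- data.frame(
        phase = i, start_s = t_cursor, end_s = t_cursor + durs[i],
        f0_base_hz = bases[i], f0_mean_hz = mean(f0_at),
        f0_sd_hz = stats::sd(f0_at))
      t_cursor <- t_cursor + durs[i]

      if (spec$include_inspiratory) {
        insp_dur <- 0.18
        gap <- 0.06
        ni <- as.integer(insp_dur * fs)
        noise <- stats::rnorm(ni)
        bf <- signal::butter(4, min(0.95, 4000 / (fs / 2)), type = "high")
        insp <- signal::filtfilt(bf, noise)
        insp <- 0.6 * spec$amplitude * insp / max(abs(insp))
        pieces[[length(pieces) + 1L]] <- numeric(as.integer(gap * fs))
        pieces[[length(pieces) + 1L]] <- insp
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          start_s = t_cursor + gap, end_s = t_cursor + gap + insp_dur,
          label = "inspiratory")
        t_cursor <- t_cursor + gap + insp_dur
      }
      pieces[[length(pieces) + 1L]] <-
        numeric(as.integer(pauses[i + 1L] * fs))
      t_cursor <- t_cursor + pauses[i + 1L]
    }
    x <- unlist(pieces)
    if (length(x) == 0L) x <- numeric(as.integer(fs))  # 1 s of silence
    if (is.finite(spec$snr_db) && any(x != 0)) {
      sig_rms <- sqrt(mean(x[x != 0]^2))
      noise_rms <- sig_rms / 10^(spec$snr_db / 20)
      x <- x + stats::rnorm(length(x), 0, noise_rms)
    }
    x <- pmin(pmax(x, -1), 1)

    rec <- structure(list(samples = x, sample_rate_hz = fs, n_channels = 1L,
                          source_path = "<synthetic>",
                          bout_start_captured = TRUE),
                     class = "audio_recording")
    list(recording = rec,
         truth = list(
           segments = do.call(rbind, seg_rows) %||%
             data.frame(start_s = numeric(0), end_s = numeric(0),
                        label = character(0)),
           phases = do.call(rbind, phase_rows) %||%
             data.frame(phase = integer(0), start_s = numeric(0),
                        end_s = numeric(0), f0_base_hz = numeric(0),
                        f0_mean_hz = numeric(0), f0_sd_hz = numeric(0)),
           spec = spec))
  })
}
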