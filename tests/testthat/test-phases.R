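seg_row <- function(start_s, end_s, label = "expiratory") {
  data.frame(start_s = start_s, end_s = end_s, label = label)
}

test_that("track_phase recovers constant and ramped contours", {
  # constant 450 Hz, no noise: mean ~450, SD at the numerical floor
  rec <- make_recording(harmonic_signal(rep(450, FS)))
  tr <- track_phase(seg_row(0, 1), rec)
  expect_lt(abs(tr$phase_f0_mean_hz - 450), 1)
  expect_lt(tr$phase_f0_sd_hz, 1)
  expect_equal(tr$inharmonic_fraction, 0)

  # 450 -> 470 Hz linear ramp: SD within 10% of the contour's SD at the
  # frame centers
  f0 <- seq(450, 470, length.out = FS)
  rec <- make_recording(harmonic_signal(f0))
  tr <- track_phase(seg_row(0, 1), rec)
  centers <- (seq_len(tr$n_frames) - 1L) * 600 + 600
  oracle_sd <- sd(f0[centers])
  expect_lt(abs(tr$phase_f0_sd_hz - oracle_sd) / oracle_sd, 0.10)
  expect_lt(abs(tr$phase_f0_mean_hz - mean(f0[centers])), 2)
})

test_that("inharmonic frames are counted and excluded from phase stats", {
  # 1800 samples of 450-Hz harmonic then noise: exactly 2 of 10 frames are
  # fully harmonic
  set.seed(5)
  x <- c(harmonic_signal(rep(450, 1800)), rnorm(4800) * 0.3)
  rec <- make_recording(pmin(pmax(x, -1), 1))
  tr <- track_phase(seg_row(0, length(x) / FS), rec)
  expect_equal(tr$n_frames, 10L)
  expect_equal(tr$inharmonic_fraction, 0.8)
  expect_equal(tr$n_retained, 2L)
  # phase statistics are computed only over the surviving frames
  expect_lt(abs(tr$phase_f0_mean_hz - 450), 2)

  # all-noise phase: no survivors, statistics absent
  set.seed(6)
  rec <- make_recording(rnorm(FS) * 0.3)
  tr <- track_phase(seg_row(0, 1), rec)
  expect_equal(tr$n_retained, 0L)
  expect_true(is.na(tr$phase_f0_mean_hz))
})

test_that("phase selection applies the duration, harmonicity and cap rules", {
  durs <- c(0.4, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1)
  tracks <- lapply(seq_along(durs), function(i)
    make_track(durs[i], start_s = i))
  sel <- select_phases(tracks)
  # 400 ms dropped; first five of the six survivors kept (600..1000 ms)
  expect_equal(vapply(sel$tracks, `[[`, numeric(1), "duration_s"),
               c(0.6, 0.7, 0.8, 0.9, 1.0))
  expect_true(sel$usable)
  expect_equal(sel$n_available, 6L)

  # an 80%-inharmonic phase is excluded wherever it sits
  tracks80 <- tracks
  tracks80[[4]] <- make_track(0.8, inharmonic_fraction = 0.8, start_s = 4)
  sel80 <- select_phases(tracks80)
  expect_equal(vapply(sel80$tracks, `[[`, numeric(1), "duration_s"),
               c(0.6, 0.7, 0.9, 1.0, 1.1))

  # exactly 70% inharmonic is kept (rule is strictly greater-than)
  tr70 <- make_track(0.8, n_frames = 20L, inharmonic_fraction = 0.7)
  expect_equal(select_phases(list(tr70))$n_available, 1L)

  # duration exactly 500 ms is excluded (rule is strictly greater-than)
  expect_equal(select_phases(list(make_track(0.5)))$n_available, 0L)

  # fewer than 3 survivors: unusable, count carried
  few <- select_phases(tracks[2:3])
  expect_false(few$usable)
  expect_equal(few$n_available, 2L)
})

test_that("phase-count filtering is monotone in both thresholds", {
  set.seed(8)
  tracks <- lapply(1:12, function(i)
    make_track(runif(1, 0.3, 1.4), n_frames = 20L,
               inharmonic_fraction = sample(0:16, 1) / 20, start_s = i))
  counts_dur <- vapply(c(300, 500, 700, 900), function(ms)
    select_phases(tracks, yin_config(min_phase_dur_ms = ms))$n_available,
    numeric(1))
  expect_true(all(diff(counts_dur) <= 0))
  counts_harm <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(mx)
    select_phases(tracks,
                  yin_config(max_inharmonic_fraction = mx))$n_available,
    numeric(1))
  expect_true(all(diff(counts_harm) <= 0))
})

test_that("feature aggregation is the arithmetic mean of phase statistics", {
  means <- c(460, 470, 450, 465, 455)
  tracks <- lapply(seq_along(means), function(i)
    make_track(0.8, f0_mean = means[i], f0_sd = 0.001, start_s = i))
  f <- compute_features(tracks)
  expect_equal(f$f0_hz, 460, tolerance = 1e-10)
  expect_equal(f$n_phases_used, 5L)
  expect_true(f$usable)

  # four phases: the mean over the available phases is used
  m4 <- c(440, 460, 480, 500)
  f4 <- compute_features(lapply(seq_along(m4), function(i)
    make_track(0.8, f0_mean = m4[i], start_s = i)))
  expect_equal(f4$f0_hz, 470, tolerance = 1e-10)

  # all-zero per-phase SDs give F0var 0
  z <- lapply(1:3, function(i) {
    tr <- make_track(0.8, start_s = i)
    tr$phase_f0_sd_hz <- 0
    tr
  })
  expect_equal(compute_features(z)$f0var_hz, 0)

  # phase-count contract
  expect_error(compute_features(tracks[1:2]), "3..5")
  expect_error(compute_features(c(tracks, tracks[1])), "3..5")
})

test_that("aggregation equals brute force over random retained frame lists", {
  set.seed(9)
  for (rep in 1:100) {
    n_ph <- sample(3:5, 1)
    tracks <- lapply(seq_len(n_ph), function(i)
      make_track(runif(1, 0.6, 1.2), f0_mean = runif(1, 300, 600),
                 f0_sd = runif(1, 1, 60), n_frames = sample(10:40, 1),
                 inharmonic_fraction = sample(0:5, 1) / 10, start_s = i))
    f <- compute_features(tracks)
    brute_means <- vapply(tracks, function(tr)
      mean(tr$frames$f0_hz[tr$frames$retained]), numeric(1))
    brute_sds <- vapply(tracks, function(tr)
      sd(tr$frames$f0_hz[tr$frames$retained]), numeric(1))
    expect_equal(f$f0_hz, mean(brute_means), tolerance = 1e-12)
    expect_equal(f$f0var_hz, mean(brute_sds), tolerance = 1e-12)
  }
})

test_that("identical audio and config give identical features", {
  sim <- synth_cry(cry_spec(n_expiratory = 3, seed = 21))
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(sim$recording$samples, p, FS, 24L)
  f1 <- cry_features(load_recording(p))$features
  f2 <- cry_features(load_recording(p))$features
  expect_identical(f1, f2)
})
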