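test_that("dwell contribution is the printed affine map on [150, 1000]", {
  expect_identical(dwell_contribution(150), 0)
  expect_identical(dwell_contribution(1000), 1)
  expect_equal(dwell_contribution(575), 0.5)
  # affine, strictly increasing, range exactly [0,1]
  xs <- seq(150, 1000, by = 25)
  ys <- dwell_contribution(xs)
  expect_true(all(diff(ys) > 0))
  expect_equal(range(ys), c(0, 1))
  expect_equal(max(abs(diff(ys, differences = 2))), 0, tolerance = 1e-12)
  expect_error(dwell_contribution(100), "excluded")
  expect_error(dwell_contribution(1100), "excluded")
})

test_that("trial validity rules fire on fixation, gaps, and transitions", {
  # clean shift at +400 ms is a valid shift with x one sample below 400
  v <- validate_trial(make_trial(400))
  expect_equal(v$status, "valid_shift")
  expect_lte(abs(v$saccade_time_ms - 400), 1000 / 300 + 1e-9)

  # no-shift trial stays valid
  expect_equal(validate_trial(make_trial(NA))$status, "valid_no_shift")

  # fixation fraction 0.60 pre-shift: insufficient fixation
  tr <- make_trial(600)
  s <- tr$samples
  pre <- which(s$time_ms <= tr$lateral_onset_ms + 600)
  off <- sample(pre, round(0.4 * length(pre)))
  tr$samples$x[off] <- 12  # on-screen but outside both AOIs
  v <- validate_trial(tr)
  expect_equal(v$status, "invalid")
  expect_equal(v$reason, "insufficient_fixation")

  # 250-ms gap in the analysis period invalidates; 150-ms gap does not
  g <- inject_gap(make_trial(700), 1100, 1350)
  expect_equal(validate_trial(g)$reason, "data_gap")
  g2 <- inject_gap(make_trial(700), 1100, 1250)
  expect_equal(validate_trial(g2)$status, "valid_shift")

  # transition inside a missing-data run
  tr <- inject_gap(make_trial(500), 1450, 1550)
  expect_equal(validate_trial(tr)$reason, "shift_in_gap")

  # gaze leaves the screen before reaching the target
  tr <- make_trial(600)
  mid <- tr$samples$time_ms > 1400 & tr$samples$time_ms < 1500
  tr$samples$x[mid] <- 30
  expect_equal(validate_trial(tr)$reason, "off_screen")
})

test_that("orienting SRT is the first target-AOI sample minus onset", {
  tr <- make_trial(300, task = "orienting", condition = "target")
  r <- orienting_latency(tr)
  expect_equal(r$status, "valid")
  expect_lte(abs(r$srt_ms - 300), 1000 / 300 + 1e-9)

  too_late <- make_trial(1200, task = "orienting", condition = "target")
  expect_equal(orienting_latency(too_late)$status, "too_late")
  expect_true(is.na(orienting_latency(too_late)$srt_ms))

  too_early <- make_trial(100, task = "orienting", condition = "target")
  expect_equal(orienting_latency(too_early)$status, "too_early")

  no_shift <- make_trial(NA, task = "orienting", condition = "target")
  expect_equal(orienting_latency(no_shift)$status, "too_late")
})

test_that("SRT recovers known noiseless latencies within one sample", {
  for (L in seq(200, 900, by = 100)) {
    r <- orienting_latency(make_trial(L, task = "orienting",
                                      condition = "target"))
    expect_lte(abs(r$srt_ms - L), 1000 / 300 + 1e-9)
  }
})

test_that("condition dwell index averages scorable trials and gates on n", {
  cfg <- scoring_config()
  s150 <- validate_trial(make_trial(150 + 4))   # one step above the floor
  sNo <- validate_trial(make_trial(NA))
  # a shift at the window floor and a no-shift trial average to ~0.5
  idx <- dwell_index_for_condition(list(validate_trial(make_trial(153.4)),
                                        sNo, sNo, sNo), cfg)
  expect_true(idx$included)

  three_no <- dwell_index_for_condition(list(sNo, sNo, sNo), cfg)
  expect_equal(three_no$index, 1)

  two <- dwell_index_for_condition(list(sNo, sNo), cfg)
  expect_false(two$included)
  expect_true(is.na(two$index))

  # invalid trials are excluded from the mean
  bad <- validate_trial(inject_gap(make_trial(500), 1100, 1400))
  mixed <- dwell_index_for_condition(list(sNo, sNo, sNo, bad), cfg)
  expect_equal(mixed$n_scorable, 3L)
  expect_equal(mixed$index, 1)
})

test_that("participant aggregation applies inclusion rules per task", {
  orient <- lapply(c(300, 400, 350, 450), function(L)
    make_trial(L, task = "orienting", condition = "target"))
  dis <- unlist(lapply(c("happy", "fearful", "nonface"), function(cc)
    lapply(c(400, 700, NA), function(L) make_trial(L, condition = cc))),
    recursive = FALSE)
  agg <- aggregate_participant(c(orient, dis))
  expect_true(agg$included_orienting)
  expect_lte(abs(agg$orienting_latency_ms - 375), 1000 / 300)
  expect_true(agg$included_dwell)
  expect_equal(unname(agg$dwell_index),
               unname(mean(agg$dwell_index_by_condition)))

  # 3 scorable orienting trials: excluded
  agg3 <- aggregate_participant(c(orient[1:3], dis))
  expect_false(agg3$included_orienting)

  # dropping one condition below 3 scorable trials excludes the dwell index
  agg_drop <- aggregate_participant(c(orient, dis[-(1:2)]))
  expect_false(agg_drop$included_dwell)
  expect_true(is.na(agg_drop$dwell_index))

  # permutation invariance
  set.seed(10)
  perm <- sample(length(c(orient, dis)))
  agg_p <- aggregate_participant(c(orient, dis)[perm])
  expect_equal(agg_p$orienting_latency_ms, agg$orienting_latency_ms)
  expect_equal(agg_p$dwell_index, agg$dwell_index)
})

test_that("unweighted condition mean matches hand computation", {
  # three conditions engineered to indices ~ {0, 1, 1}
  mk <- function(cc, Ls) lapply(Ls, function(L) make_trial(L, condition = cc))
  trials <- c(mk("happy", c(153.4, 153.4, 153.4)),
              mk("fearful", c(NA, NA, NA)),
              mk("nonface", c(NA, NA, NA)))
  agg <- aggregate_participant(trials)
  expect_equal(unname(agg$dwell_index),
               mean(c(agg$dwell_index_by_condition[["happy"]], 1, 1)))
  expect_lt(agg$dwell_index_by_condition[["happy"]], 0.01)
})

test_that("gaze files round-trip through the CSV contract", {
  sim <- synth_gaze(gaze_spec(n_orienting_trials = 2L,
                              n_disengagement_per_condition = 1L,
                              seed = 4))
  gp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim$gaze, gp, row.names = FALSE)
  write.csv(sim$events, ep, row.names = FALSE)
  trials <- read_gaze_file(gp, ep)
  expect_length(trials, 5L)
  n_per <- table(sim$gaze$trial_id)
  expect_equal(unname(vapply(trials, function(tr) nrow(tr$samples),
                             numeric(1))),
               unname(as.numeric(n_per[vapply(trials, `[[`, character(1),
                                              "trial_id")])))
  # ~300 samples per second of trial
  expect_equal(nrow(trials[[1]]$samples),
               length(seq(0, 2200, by = 1000 / 300)))

  # orphan trial (no events row) is named in the error
  ev2 <- read.csv(ep)[-1, ]
  ep2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(ev2, ep2, row.names = FALSE)
  expect_error(read_gaze_file(gp, ep2), "T001")

  # missing column is rejected
  g2 <- read.csv(gp)
  g2$valid <- NULL
  gp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(g2, gp2, row.names = FALSE)
  expect_error(read_gaze_file(gp2, ep), "valid")
})
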