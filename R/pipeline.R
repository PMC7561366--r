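# End-to-end orchestration: configuration, gaze-session scoring over files,
# the participant join, the cohort report, and the run manifest.

#' Score a gaze session file into participant attention measures
#'
#' Reads the gaze and events CSVs, groups trials by the events'
#' \code{participant_id} column (all trials form one participant when the
#' column is absent), and aggregates each participant with
#' \code{\link{aggregate_participant}}.
#'
#' @param gaze_path,events_path CSV paths (see \code{\link{read_gaze_file}}).
#' @param cfg A \code{\link{scoring_config}}.
#' @return A data.frame with one row per participant:
#'   \code{participant_id}, \code{orienting_latency_ms},
#'   \code{n_orienting_trials}, \code{included_orienting},
#'   \code{dwell_happy}, \code{dwell_fearful}, \code{dwell_nonface},
#'   \code{dwell_index}, \code{included_dwell}.
#' @export
score_gaze_files <- function(gaze_path, events_path,
                             cfg = scoring_config()) {
  trials <- read_gaze_file(gaze_path, events_path)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  pid_of <- if ("participant_id" %in% names(events)) {
    stats::setNames(as.character(events$participant_id), events$trial_id)
  } else {
    stats::setNames(rep("P1", nrow(events)), events$trial_id)
  }
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  rows <- lapply(unique(pid_of[ids]), function(pid) {
    agg <- aggregate_participant(trials[pid_of[ids] == pid], cfg)
    data.frame(
      participant_id = pid,
      orienting_latency_ms = agg$orienting_latency_ms,
      n_orienting_trials = agg$n_orienting_trials,
      included_orienting = agg$included_orienting,
      dwell_happy = agg$dwell_index_by_condition[["happy"]],
      dwell_fearful = agg$dwell_index_by_condition[["fearful"]],
      dwell_nonface = agg$dwell_index_by_condition[["nonface"]],
      dwell_index = agg$dwell_index,
      included_dwell = agg$included_dwell
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' One configuration governs all stages so cohort-specific parameterizations
#' are explicit profiles rather than code branches. The input block selects
#' the run mode: \code{"simulate_cohort"} draws participant-level cohorts
#' directly; \code{"files"} reads a prepared participant CSV (the join of
#' the cry-feature and gaze-score outputs).
#'
#' @param seed Master seed for all simulated inputs.
#' @param out_dir Directory for the report bundle.
#' @param input A list: either \code{list(mode = "simulate_cohort",
#'   specs = list(<cohort_spec>, ...))} or \code{list(mode = "files",
#'   participants_csv = <path>)}.
#' @param yin,seg,scoring Stage configurations.
#' @param d_denominator Cohen's d pooling convention (see
#'   \code{\link{pooled_t_test}}).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("crygaze_run_"),
                       input = list(mode = "simulate_cohort",
                                    specs = NULL),
                       yin = yin_config(), seg = seg_config(),
                       scoring = scoring_config(),
                       d_denominator = "total") {
  .assert(input$mode %in% c("simulate_cohort", "files"),
          "unknown input mode: %s", input$mode)
  if (input$mode == "files") {
    .assert(file.exists(input$participants_csv),
            "participants file does not exist: %s", input$participants_csv)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir, input = input,
                 yin = yin, seg = seg, scoring = scoring,
                 d_denominator = d_denominator), class = "run_config")
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  # drop the output path so the fingerprint identifies the analysis, not
  # where it was written
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg <- rapply(cfg, unclass, how = "replace")
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full cohort analysis
#'
#' Assembles the participant table (simulated cohorts or a prepared CSV),
#' computes the descriptive table, the cohort-comparison t-tests, and the
#' cohort x subset correlation table, and writes the report bundle:
#' \code{participants.csv}, \code{descriptives.csv}, \code{t_tests.csv},
#' \code{correlations.csv}, \code{report.json}, and \code{manifest.json}
#' (config fingerprint, seed, versions, per-stage row counts).
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with \code{participants}, \code{descriptives},
#'   \code{t_tests}, \code{correlations}, \code{manifest}, \code{out_dir}.
#' @export
run_pipeline <- function(config = run_config()) {
  participants <- if (config$input$mode == "simulate_cohort") {
    specs <- config$input$specs %||% list(
      cohort_spec(seed = config$seed),
      cape_town_spec(seed = config$seed + 1L))
    do.call(rbind, lapply(specs, function(sp) synth_cohort(sp)$participants))
  } else {
    utils::read.csv(config$input$participants_csv,
                    stringsAsFactors = FALSE)
  }
  need <- c("participant_id", "cohort", COHORT_VARS)
  .assert(all(need %in% names(participants)),
          "participant table missing columns: %s",
          paste(setdiff(need, names(participants)), collapse = ", "))

  desc <- run_descriptives_table(participants)
  tt <- run_cohort_t_tests(participants,
                           d_denominator = config$d_denominator)
  corr <- run_correlation_table(participants)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config_md5 = config_fingerprint(config),
    seed = config$seed,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("crygaze")),
    n_participants = nrow(participants),
    n_descriptive_rows = nrow(desc),
    n_t_tests = nrow(tt),
    n_correlation_cells = nrow(corr)
  )
  utils::write.csv(participants,
                   file.path(config$out_dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(desc, file.path(config$out_dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(tt, file.path(config$out_dir, "t_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(corr, file.path(config$out_dir, "correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(descriptives = desc, t_tests = tt,
                            correlations = corr),
                       file.path(config$out_dir, "report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(participants = participants, descriptives = desc,
                 t_tests = tt, correlations = corr, manifest = manifest,
                 out_dir = config$out_dir))
}
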