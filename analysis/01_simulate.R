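#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Produces (a) a small set of cry recordings as WAV files with known
# per-phase F0 structure, (b) raw gaze sessions (samples + events CSVs) with
# known saccade latencies, and (c) two participant-level cohorts drawn at
# the published descriptive parameters for the cohort-statistics arm.
# Audio goes to scratch/ (binary, regenerated on demand); tables and truth
# records go to results/sim/.

suppressPackageStartupMessages(library(crygaze))

seed <- 20260924L
audio_dir <- "scratch/audio"
sim_dir <- "results/sim"
dir.create(audio_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

n_measured <- 6L  # participants with full measurement arms

cat("simulating", n_measured, "participants with cry audio + gaze sessions\n")
truth_rows <- list()
for (i in seq_len(n_measured)) {
  pid <- sprintf("P%02d", i)
  cry <- synth_cry(cry_spec(n_expiratory = 5L, snr_db = 20,
                            include_inspiratory = TRUE, seed = seed + i))
  write_wav(cry$recording$samples, file.path(audio_dir,
                                             paste0(pid, ".wav")),
            sample_rate_hz = 48000L, bit_depth = 24L)
  write.csv(cry$truth$phases,
            file.path(sim_dir, paste0(pid, "_cry_truth.csv")),
            row.names = FALSE)

  gz <- synth_gaze(gaze_spec(seed = seed + 100L + i), participant_id = pid)
  write.csv(gz$gaze, file.path(sim_dir, paste0(pid, "_gaze.csv")),
            row.names = FALSE)
  write.csv(gz$events, file.path(sim_dir, paste0(pid, "_events.csv")),
            row.names = FALSE)
  write.csv(gz$truth, file.path(sim_dir, paste0(pid, "_gaze_truth.csv")),
            row.names = FALSE)
  truth_rows[[i]] <- data.frame(
    participant_id = pid,
    true_f0_hz = mean(cry$truth$phases$f0_mean_hz),
    true_f0var_hz = mean(cry$truth$phases$f0_sd_hz))
}
write.csv(do.call(rbind, truth_rows),
          file.path(sim_dir, "measured_truth.csv"), row.names = FALSE)

cat("simulating the two participant-level cohorts at the published",
    "descriptive parameters\n")
coh_t <- synth_cohort(cohort_spec(corr = corr_with("f0_hz", "dwell_index",
                                                   0.29),
                                  seed = seed))
coh_c <- synth_cohort(cape_town_spec(seed = seed + 1L))
participants <- rbind(coh_t$participants, coh_c$participants)
write.csv(participants, file.path(sim_dir, "participants.csv"),
          row.names = FALSE)

cat("wrote", n_measured, "WAVs to", audio_dir, "and",
    nrow(participants), "cohort participants to",
    file.path(sim_dir, "participants.csv"), "\n")
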