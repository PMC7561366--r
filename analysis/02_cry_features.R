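#!/usr/bin/env Rscript
# Stage 2: the acoustic arm.
#
# Runs every simulated cry recording through segmentation, YIN pitch
# tracking, and the phase filters, and compares the recovered F0 / F0var
# against the generator truth.

suppressPackageStartupMessages(library(crygaze))

audio_dir <- "scratch/audio"
sim_dir <- "results/sim"
wavs <- sort(list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE))
stopifnot(length(wavs) > 0)

res <- extract_cry_features(wavs, bout_start_captured = TRUE)
write.csv(res$features, "results/cry_features.csv", row.names = FALSE)
write.csv(res$diagnostics, "results/cry_diagnostics.csv", row.names = FALSE)

truth <- read.csv(file.path(sim_dir, "measured_truth.csv"))
cmp <- merge(res$features, truth,
             by.x = "recording_id", by.y = "participant_id")
cmp$f0_rel_err <- abs(cmp$f0_hz - cmp$true_f0_hz) / cmp$true_f0_hz
cat(sprintf("%d/%d recordings usable\n", sum(cmp$usable), nrow(cmp)))
cat(sprintf("max relative F0 error: %.3f%%\n", 100 * max(cmp$f0_rel_err)))
cat(sprintf("F0var recovered within %.1f Hz of truth on average\n",
            mean(abs(cmp$f0var_hz - cmp$true_f0var_hz))))
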