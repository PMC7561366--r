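Package: crygaze
Title: Neonatal Cry Acoustics and Infant Visual Attention Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible two-armed analysis pipeline linking neonatal cry
    acoustics to infant visual attention. The acoustic arm extracts the cry
    fundamental frequency (F0) and its within-phase variability (F0var) from
    WAV recordings using expiratory-phase segmentation and a YIN
    (cumulative-mean-normalized difference) pitch tracker with explicit
    aperiodicity, duration, and harmonicity filtering rules. The attention arm
    scores raw eye-tracking gaze streams into oculomotor-orienting saccadic
    reaction times and a normalized attention-disengagement dwell-time index.
    A cohort-statistics layer produces descriptives, pooled t-tests with
    Cohen's d, and two-tailed Pearson correlation tables with subgroup
    filters. Seed-deterministic synthetic generators for cry audio, gaze
    streams, and participant cohorts provide ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
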