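#!/usr/bin/env Rscript
# Simulate the emulated ambiguity study: a randomized stimulus schedule
# shared by all subjects, and per-subject multichannel EEG epochs in which
# high-ambiguity (HA) trials carry three band-limited oscillatory power
# increases over 1/f background noise.

suppressPackageStartupMessages(library(erspcluster))
source("analysis/00_settings.R")

mtg <- default_montage()
schedule <- generate_schedule(N_PER_CONTRAST, seed = SEED)
effects <- default_effects(gain = EFFECT_GAIN)

cat(sprintf("schedule: %d trials (%d LA / %d HA), %d contrasts\n",
            nrow(schedule), sum(schedule$class_label == "LA"),
            sum(schedule$class_label == "HA"),
            length(unique(schedule$contrast_I))))

epochs <- generate_epochs(N_SUBJECTS, schedule, effects = effects,
                          mtg = mtg, fs = FS, window = WINDOW, seed = SEED)
cat(sprintf("simulated %d subjects x %d trials x %d channels x %d samples\n",
            length(epochs), dim(epochs[[1]]$data)[1],
            dim(epochs[[1]]$data)[2], dim(epochs[[1]]$data)[3]))

write_montage(mtg, res_path("montage.csv"))
write.csv(as.data.frame(schedule), res_path("schedule.csv"),
          row.names = FALSE)
saveRDS(list(epochs = epochs, schedule = schedule, effects = effects),
        res_path("01_epochs.rds"))
cat("wrote results/montage.csv, results/schedule.csv, results/01_epochs.rds\n")
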