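#!/usr/bin/env Rscript
# Leave-one-subject-out classification: for every fold the small CNN is
# trained on all other subjects' topograms and tested on the held-out
# subject, emulating a pre-trained decoder meeting a naive user.

suppressPackageStartupMessages(library(erspcluster))
source("analysis/00_settings.R")

stacks <- readRDS(res_path("04_stacks.rds"))
cfg <- cnn_config(input_size = TOPO_GRID, epochs = CNN_EPOCHS, lr = 2e-3,
                  seed = SEED)
res <- run_loso(stacks, cfg)

print(res$per_fold, row.names = FALSE)
cat(sprintf("LOSO accuracy: mean %.3f, SD %.3f over %d folds\n",
            res$mean_accuracy, res$sd_accuracy, nrow(res$per_fold)))

write.csv(res$per_fold, res_path("eval.csv"), row.names = FALSE)
jsonlite::write_json(list(mean_accuracy = res$mean_accuracy,
                          sd_accuracy = res$sd_accuracy),
                     res_path("eval_summary.json"), auto_unbox = TRUE,
                     digits = NA)
saveRDS(res, res_path("05_loso.rds"))
cat("wrote results/eval.csv, results/eval_summary.json, results/05_loso.rds\n")
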