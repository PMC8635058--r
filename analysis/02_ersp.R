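#!/usr/bin/env Rscript
# Morlet-wavelet ERSP per trial, then subject-mean ERSP per condition.
# The wavelet uses the n = f cycles rule (constant 0.159-s temporal width)
# and the prestimulus interval [-0.5, 0) s as the relative-change baseline.

suppressPackageStartupMessages(library(erspcluster))
source("analysis/00_settings.R")

sim <- readRDS(res_path("01_epochs.rds"))
wpars <- wavelet_params(freqs = FREQS, times = TIMES)

means_ha <- list(); means_la <- list(); trial_ersp <- list()
for (k in seq_along(sim$epochs)) {
  er <- compute_ersp(wavelet_power(sim$epochs[[k]], wpars))
  means_ha[[k]] <- average_ersp(er, sim$schedule$class_label, "HA")
  means_la[[k]] <- average_ersp(er, sim$schedule$class_label, "LA")
  trial_ersp[[k]] <- er
}
ha <- subject_mean_stack(means_ha)
la <- subject_mean_stack(means_la)

# grand means inside/outside the first injected effect box, as a sanity
# summary of what the contrast will see
e1 <- sim$effects[[1]]
fi <- FREQS >= e1$f_lo & FREQS <= e1$f_hi
ti <- TIMES >= e1$t_lo & TIMES <= e1$t_hi
chs <- match(e1$channels, default_montage()$name)
d <- apply(ha - la, c(2, 3, 4), mean)
cat(sprintf("grand-mean HA-LA ERSP inside effect-1 box: %.3f\n",
            mean(d[chs, fi, ti])))
cat(sprintf("outside all boxes (first channel/frequency): %.3f\n",
            mean(d[-chs, !fi, !ti])))

saveRDS(list(ha = ha, la = la, trial_ersp = trial_ersp),
        res_path("02_ersp.rds"))
cat("wrote results/02_ersp.rds\n")
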