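# Shared settings for the analysis scripts: a desk-scale emulation of the
# ambiguity study (10 subjects, 100 LA + 100 HA trials each, 31 channels,
# 4-22 Hz on a 2-Hz grid). The full-scale emulation (20 subjects, 4-40 Hz
# at 1 Hz, 2000 permutations) uses the same code through run_pipeline();
# these sizes keep every script in the minutes range on one CPU. The trial
# count is kept at the study's 100 per class: the cluster contrast needs
# subject-mean ERSPs with study-scale trial averaging to stabilise the
# heavy-tailed per-trial baseline ratios.

SEED <- 20260930
N_SUBJECTS <- 12
N_PER_CONTRAST <- 25          # 100 trials per class
FS <- 100
WINDOW <- c(-1, 1)
EFFECT_GAIN <- 4
FREQS <- seq(4, 34, 2)
TIMES <- seq(-0.5, 0.45, by = 0.05)
N_PERM <- 500
TOPO_GRID <- 32
CNN_EPOCHS <- 12

RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

res_path <- function(...) file.path(RESULTS, ...)
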