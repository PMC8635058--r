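#!/usr/bin/env Rscript
# Feature extraction: paired cluster-based permutation contrast of the
# subject-mean ERSP between HA and LA over (channel, frequency, time)
# triplets (elementwise p = 0.01 two-tailed, >= 2 spatial neighbours,
# summed rectified t, per-polarity max-mass null, cluster p < 0.025).

suppressPackageStartupMessages(library(erspcluster))
source("analysis/00_settings.R")

er <- readRDS(res_path("02_ersp.rds"))
g <- channel_neighbors(default_montage())

contrast <- cluster_contrast(er$ha, er$la, graph = g, n_perm = N_PERM,
                             seed = SEED)
write_cluster_report(contrast, res_path("clusters.json"),
                     res_path("clusters.tsv"))

sig <- significant_clusters(contrast)
cat(sprintf("%d cluster(s) formed, %d significant at p < 0.025:\n",
            length(contrast$clusters), length(sig)))
for (cl in sig)
  cat(sprintf("  %s  f = [%.1f, %.1f] Hz  t = [%.2f, %.2f] s  mass = %.0f  p = %.4f\n",
              cl$polarity, cl$f_bounds[1], cl$f_bounds[2],
              cl$t_bounds[1], cl$t_bounds[2], cl$mass, cl$p_value))

saveRDS(contrast, res_path("03_contrast.rds"))
cat("wrote results/clusters.json, results/clusters.tsv, results/03_contrast.rds\n")
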