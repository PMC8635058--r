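#!/usr/bin/env Rscript
# Scalp topograms: for every significant cluster, average each trial's
# ERSP over the cluster's time-frequency box and interpolate the 31
# channel values over the head disc (thin-plate spline), under colour
# limits fixed across the whole run.

suppressPackageStartupMessages(library(erspcluster))
source("analysis/00_settings.R")

er <- readRDS(res_path("02_ersp.rds"))
contrast <- readRDS(res_path("03_contrast.rds"))
sim <- readRDS(res_path("01_epochs.rds"))
sig <- significant_clusters(contrast)
if (length(sig) == 0) stop("no significant clusters; nothing to render")

interp <- topo_interpolator(default_montage(), TOPO_GRID)
vals <- lapply(er$trial_ersp, function(trial_er)
  lapply(sig, function(cl) cluster_average(trial_er, cluster = cl)))
lims <- compute_color_limits(unlist(vals))
cat(sprintf("colour limits fixed at [%.2f, %.2f]\n", lims[1], lims[2]))

stacks <- lapply(seq_along(vals), function(k)
  build_topogram_stack(vals[[k]], sim$schedule$class_label, interp, lims,
                       subject_id = k))
counts <- vapply(stacks, stack_size, numeric(1))
cat(sprintf("%d subjects x %d images (%d trials x %d clusters)\n",
            length(stacks), counts[1], dim(stacks[[1]]$images)[1],
            length(sig)))

# a handful of example PNGs for visual inspection
if (requireNamespace("png", quietly = TRUE)) {
  ex <- stacks[[1]]
  ex$images <- ex$images[1:4, , , , drop = FALSE]
  ex$labels <- ex$labels[1:4]; ex$trial_ids <- ex$trial_ids[1:4]
  write_topogram_png(ex, res_path("topogram_examples"))
  cat("wrote results/topogram_examples/*.png\n")
}

saveRDS(stacks, res_path("04_stacks.rds"))
cat("wrote results/04_stacks.rds\n")
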