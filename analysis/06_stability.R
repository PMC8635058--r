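#!/usr/bin/env Rscript
# Stability of the extracted features: re-run the cluster contrast with
# each subject excluded, quantify the bound changes as delta-f / delta-t
# percent metrics, and regress per-subject LOSO accuracy on the time
# deltas.

suppressPackageStartupMessages(library(erspcluster))
source("analysis/00_settings.R")

er <- readRDS(res_path("02_ersp.rds"))
loso <- readRDS(res_path("05_loso.rds"))
g <- channel_neighbors(default_montage())

stab <- stability_analysis(er$ha, er$la, g,
                           list(n_perm = N_PERM, seed = SEED))
write.csv(stab$records, res_path("stability.csv"), row.names = FALSE)
cat(sprintf("stability records: %d rows (%d clusters x %d subjects)\n",
            nrow(stab$records), length(significant_clusters(stab$common)),
            dim(er$ha)[1]))
present <- stab$records[stab$records$present, , drop = FALSE]
cat(sprintf("cluster present in %d of %d leave-one-out runs\n",
            nrow(present), nrow(stab$records)))
if (nrow(present) > 0) {
  agg <- aggregate(cbind(delta_f, delta_t) ~ cluster, present, mean)
  cat("mean bound change per cluster (percent):\n")
  print(agg, row.names = FALSE)
}

# accuracy ~ delta_t regression: clusters absent from most leave-one-out
# runs carry no usable delta and are dropped as predictors; subjects
# missing any remaining cluster are excluded (complete cases)
pres_rate <- tapply(stab$records$present, stab$records$cluster, mean)
usable <- as.integer(names(pres_rate)[pres_rate >= 2 / 3])
cat(sprintf("clusters usable as predictors: %s\n",
            paste(usable, collapse = ", ")))
rec_u <- stab$records[stab$records$cluster %in% usable,
                      c("excluded_subject", "cluster", "delta_t")]
wide <- reshape(rec_u, idvar = "excluded_subject", timevar = "cluster",
                direction = "wide")
names(wide) <- sub("delta_t\\.", "delta_t_", names(wide))
acc <- loso$per_fold$accuracy[match(wide$excluded_subject,
                                    loso$per_fold$test_subject)]
reg <- tryCatch(
  accuracy_regression(acc, wide[, -1, drop = FALSE]),
  error = function(e) { cat("regression not estimable:", conditionMessage(e), "\n"); NULL })
if (!is.null(reg)) {
  cat(sprintf("accuracy ~ delta_t: R^2 = %.3f, F(%d, %d) = %.2f, p = %.3f\n",
              reg$r_squared, reg$df[1], reg$df[2], reg$f_statistic,
              reg$p_value))
  jsonlite::write_json(
    list(r_squared = reg$r_squared, f = reg$f_statistic, p = reg$p_value,
         coefficients = as.list(reg$coefficients),
         std_beta = as.list(reg$std_beta), n = reg$n),
    res_path("regression.json"), auto_unbox = TRUE, digits = NA)
  cat("wrote results/regression.json\n")
}
cat("wrote results/stability.csv\n")
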