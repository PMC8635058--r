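# Stability of cluster bounds under subject exclusion: re-run the cluster
# contrast with each subject left out, match the resulting clusters to the
# all-subject ("common") ones, and quantify the bound change as a percent
# of twice the common width:
#
#   delta = (|lower_ind - lower_com| + |upper_ind - upper_com|)
#           / (2 * (upper_com - lower_com)) * 100%
#
# computed separately on the frequency and the time axis. The deltas feed
# an ordinary least-squares regression of per-subject classification
# accuracy on the per-cluster deltas.

.delta_interval <- function(common, individual, what) {
  stopifnot(length(common) == 2, length(individual) == 2)
  width <- common[2] - common[1]
  if (width <= 0) stop("zero-width common ", what, " interval")
  (abs(individual[1] - common[1]) + abs(individual[2] - common[2])) /
    (2 * width) * 100
}

#' Percent change of a cluster's frequency bounds
#'
#' @param common `c(f1, f2)` bounds from the all-subject run, Hz.
#' @param individual `c(f1, f2)` bounds from a leave-one-out run, Hz.
#' @return non-negative percent; 0 iff the intervals coincide. The measure
#'   is scale-covariant: expressing both intervals in other units leaves
#'   the percent unchanged.
#' @export
#' @examples
#' delta_f(c(7.25, 8.5), c(7.45, 8.3))  # 16
delta_f <- function(common, individual) {
  .delta_interval(common, individual, "frequency")
}

#' Percent change of a cluster's time bounds
#'
#' Same form as [delta_f()] on the time axis.
#' @param common,individual `c(t1, t2)` intervals in seconds.
#' @return non-negative percent.
#' @export
delta_t <- function(common, individual) {
  .delta_interval(common, individual, "time")
}

# time-frequency box overlap area between two clusters (same polarity)
.box_overlap <- function(a, b) {
  fo <- max(0, min(a$f_bounds[2], b$f_bounds[2]) -
              max(a$f_bounds[1], b$f_bounds[1]))
  to <- max(0, min(a$t_bounds[2], b$t_bounds[2]) -
              max(a$t_bounds[1], b$t_bounds[1]))
  fo * to
}

#' Re-extract cluster bounds with one subject excluded
#'
#' Re-runs the full cluster contrast on the remaining subjects with
#' settings identical to the common run, and matches each common
#' significant cluster to the leave-one-out significant cluster of the
#' same polarity with maximal time-frequency box overlap. Unmatched
#' clusters are recorded as absent (`present = FALSE`), never imputed.
#'
#' @param ha,la subject x channel x frequency x time subject-mean stacks
#'   (all subjects).
#' @param excluded subject index to leave out.
#' @param graph,settings neighbourhood graph and a list of
#'   [cluster_contrast()] arguments (`alpha`, `cluster_alpha`, `n_perm`,
#'   `min_channel_neighbors`, `seed`, `time_window`).
#' @param common the all-subject `cluster_result` (computed if `NULL`).
#' @return data frame: one row per common significant cluster with the
#'   individual bounds, `present`, `delta_f`, `delta_t` (NA when absent).
#' @export
loso_cluster_bounds <- function(ha, la, excluded, graph, settings = list(),
                                common = NULL) {
  n <- dim(ha)[1]
  stopifnot(n - 1 >= 3, excluded >= 1, excluded <= n)
  run <- function(h, l) {
    do.call(cluster_contrast,
            c(list(ha = h, la = l, graph = graph), settings))
  }
  sub <- function(a, keep) {
    out <- a[keep, , , , drop = FALSE]
    for (at in c("freqs", "times", "channels"))
      attr(out, at) <- attr(a, at)
    out
  }
  if (is.null(common)) common <- run(ha, la)
  ind <- run(sub(ha, setdiff(seq_len(n), excluded)),
             sub(la, setdiff(seq_len(n), excluded)))
  com_sig <- significant_clusters(common)
  ind_sig <- significant_clusters(ind)
  rows <- lapply(seq_along(com_sig), function(i) {
    cc <- com_sig[[i]]
    cand <- Filter(function(cl) cl$polarity == cc$polarity, ind_sig)
    ov <- vapply(cand, .box_overlap, numeric(1), a = cc)
    if (length(ov) == 0 || max(ov) <= 0) {
      return(data.frame(excluded_subject = excluded, cluster = i,
                        present = FALSE, f1_ind = NA_real_, f2_ind = NA_real_,
                        t1_ind = NA_real_, t2_ind = NA_real_,
                        delta_f = NA_real_, delta_t = NA_real_))
    }
    m <- cand[[which.max(ov)]]
    data.frame(excluded_subject = excluded, cluster = i, present = TRUE,
               f1_ind = m$f_bounds[1], f2_ind = m$f_bounds[2],
               t1_ind = m$t_bounds[1], t2_ind = m$t_bounds[2],
               delta_f = delta_f(cc$f_bounds, m$f_bounds),
               delta_t = delta_t(cc$t_bounds, m$t_bounds))
  })
  do.call(rbind, rows)
}

#' Full leave-one-subject-out stability analysis
#'
#' Runs [loso_cluster_bounds()] for every subject against the common run.
#'
#' @inheritParams loso_cluster_bounds
#' @return list with `common` (the all-subject `cluster_result`) and
#'   `records` (data frame, one row per excluded subject x common
#'   significant cluster).
#' @export
stability_analysis <- function(ha, la, graph, settings = list()) {
  common <- do.call(cluster_contrast,
                    c(list(ha = ha, la = la, graph = graph), settings))
  recs <- lapply(seq_len(dim(ha)[1]), function(k)
    loso_cluster_bounds(ha, la, k, graph, settings, common = common))
  list(common = common, records = do.call(rbind, recs))
}

#' Regress classification accuracy on cluster-bound changes
#'
#' Ordinary least squares of per-subject LOSO accuracy on the per-cluster
#' delta metrics (complete cases only: subjects missing any cluster are
#' excluded). Reports coefficients, standardized betas, R-squared and the
#' overall F test.
#'
#' @param accuracy per-subject accuracies (response).
#' @param deltas data frame of predictors, one column per cluster delta
#'   (e.g. `delta_t_1 .. delta_t_3`), rows aligned with `accuracy`.
#' @return a `regression_result`: `coefficients`, `std_beta`,
#'   `r_squared`, `f_statistic`, `df`, `p_value`, `coef_p`, `n`.
#' @export
accuracy_regression <- function(accuracy, deltas) {
  stopifnot(is.data.frame(deltas), length(accuracy) == nrow(deltas))
  cc <- complete.cases(deltas) & is.finite(accuracy)
  y <- accuracy[cc]
  X <- deltas[cc, , drop = FALSE]
  if (length(y) < ncol(X) + 2)
    stop("rank error: fewer complete cases than predictors + 2")
  if (any(vapply(X, function(v) var(v) == 0, logical(1))))
    stop("rank error: zero-variance predictor")
  fit <- lm(y ~ ., data = cbind(y = y, X))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  beta <- coef(fit)[-1] * vapply(X, sd, numeric(1)) / sd(y)
  structure(list(
    coefficients = coef(fit),
    std_beta = beta,
    r_squared = sm$r.squared,
    f_statistic = unname(fstat["value"]),
    df = unname(fstat[c("numdf", "dendf")]),
    p_value = unname(pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                        lower.tail = FALSE)),
    coef_p = sm$coefficients[, "Pr(>|t|)"],
    n = length(y)), class = "regression_result")
}
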