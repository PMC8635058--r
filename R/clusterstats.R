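# Paired cluster-based permutation contrast of subject-mean ERSP over
# (channel, frequency, time) triplets.
#
# Procedure: an elementwise paired t-test (HA minus LA across subjects)
# yields a t-map; triplets exceeding the two-tailed alpha = 0.01 Student
# threshold are kept if at least `min_channel_neighbors` of their spatial
# channel neighbours (same frequency/time bin) are suprathreshold with the
# same sign; surviving triplets are grouped into connected components
# (channel adjacency from the montage graph, +/-1 bin on the frequency and
# time axes, no diagonal steps, same sign); each cluster is scored by its
# summed rectified t ("mass") and referred to the permutation distribution
# of the per-polarity maximum mass under subject-level sign flips of the
# within-subject difference. Family-wise error is controlled per tail.

#' Elementwise paired t-map
#'
#' Paired t statistic of the per-subject difference `d = HA - LA` at every
#' (channel, frequency, time) triplet: `t = mean(d) / (sd(d)/sqrt(N))`,
#' `df = N - 1`. Triplets with zero difference variance are degenerate;
#' their t is set to 0 with a warning.
#'
#' @param ha,la subject x channel x frequency x time arrays of subject-mean
#'   ERSP (axes aligned), e.g. from [subject_mean_stack()].
#' @return channel x frequency x time t-value array with attribute `df`.
#' @export
paired_t_map <- function(ha, la) {
  stopifnot(identical(dim(ha), dim(la)), dim(ha)[1] >= 2)
  n <- dim(ha)[1]
  D <- matrix(ha - la, nrow = n)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0  # numerical guard
  degen <- s2 <= .Machine$double.eps * 100
  t <- m / sqrt(s2 / n)
  if (any(degen)) {
    warning(sum(degen), " triplet(s) with zero difference variance; t set to 0")
    t[degen] <- 0
  }
  t[!is.finite(t)] <- 0
  out <- array(t, dim = dim(ha)[-1])
  structure(out, df = n - 1, freqs = attr(ha, "freqs"),
            times = attr(ha, "times"), channels = attr(ha, "channels"))
}

# connected components of suprathreshold triplets for one polarity.
# mask: logical (ch, f, t) array; adj: list of integer channel neighbours.
# Returns list of integer-matrix member sets (columns ch, f, t).
.components <- function(mask, adj) {
  dm <- dim(mask)
  nch <- dm[1]; nf <- dm[2]; nt <- dm[3]
  keep <- which(mask)
  if (length(keep) == 0) return(list())
  rank <- integer(length(mask)); rank[keep] <- seq_along(keep)
  visited <- logical(length(keep))
  comps <- list()
  # decode linear index -> (ch, f, t)
  ch_of <- ((keep - 1L) %% nch) + 1L
  f_of <- (((keep - 1L) %/% nch) %% nf) + 1L
  t_of <- ((keep - 1L) %/% (nch * nf)) + 1L
  for (s in seq_along(keep)) {
    if (visited[s]) next
    stack <- s
    visited[s] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      ch <- ch_of[cur]; fi <- f_of[cur]; ti <- t_of[cur]
      base_ft <- (fi - 1L) * nch + (ti - 1L) * nch * nf
      cand <- c(adj[[ch]] + base_ft,
                if (fi > 1L) keep[cur] - nch,
                if (fi < nf) keep[cur] + nch,
                if (ti > 1L) keep[cur] - nch * nf,
                if (ti < nt) keep[cur] + nch * nf)
      r <- rank[cand]
      r <- r[r > 0L]
      r <- r[!visited[r]]
      if (length(r)) {
        visited[r] <- TRUE
        stack <- c(stack, r)
      }
    }
    comps[[length(comps) + 1L]] <- cbind(ch = ch_of[members],
                                         f = f_of[members],
                                         t = t_of[members])
  }
  comps
}

# spatial neighbour pruning: keep suprathreshold triplets having at least
# min_nb suprathreshold channel-neighbours (same sign, same f/t bin)
.prune_neighbors <- function(mask, adj_mat, min_nb) {
  if (min_nb <= 0) return(mask)
  dm <- dim(mask)
  m2 <- matrix(mask, nrow = dm[1])             # ch x (f*t)
  counts <- adj_mat %*% m2                     # neighbour counts
  mask & array(counts >= min_nb, dim = dm)
}

#' Threshold a t-map and form clusters
#'
#' Marks triplets whose |t| exceeds the two-tailed Student threshold at
#' `alpha`, applies the minimum spatial-neighbour criterion, and collects
#' the survivors into sign-separated connected components under channel
#' adjacency and +/-1 frequency/time bin adjacency (no diagonal steps).
#'
#' @param tmap channel x frequency x time t array (attribute `df` used when
#'   `df` missing).
#' @param df degrees of freedom of the t statistic.
#' @param alpha two-tailed elementwise threshold probability (default 0.01).
#' @param graph a [channel_neighbors()] graph matching the t-map's channel
#'   order.
#' @param min_channel_neighbors minimum number of suprathreshold same-sign
#'   spatial neighbours required to keep a triplet (default 2; 0 disables).
#' @return list of `ersp_cluster` objects (fields `members`, `polarity`,
#'   `mass`), sorted by decreasing mass.
#' @export
threshold_and_cluster <- function(tmap, df = attr(tmap, "df"), alpha = 0.01,
                                  graph, min_channel_neighbors = 2) {
  stopifnot(df >= 1)
  adj_mat <- attr(graph, "adjacency")
  stopifnot(nrow(adj_mat) == dim(tmap)[1])
  adj <- lapply(seq_len(nrow(adj_mat)), function(i) which(adj_mat[i, ]))
  thr <- qt(1 - alpha / 2, df)
  out <- list()
  for (pol in c("positive", "negative")) {
    mask <- if (pol == "positive") unclass(tmap) > thr else unclass(tmap) < -thr
    mask <- .prune_neighbors(mask, adj_mat, min_channel_neighbors)
    for (mem in .components(mask, adj)) {
      mass <- sum(abs(tmap[cbind(mem[, 1], mem[, 2], mem[, 3])]))
      out[[length(out) + 1L]] <- structure(
        list(members = mem, polarity = pol, mass = mass), class = "ersp_cluster")
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "mass"), decreasing = TRUE)]
}

# max cluster mass per polarity for one t-map (0 when no cluster)
.max_masses <- function(tmap, df, alpha, adj_mat, adj, min_nb) {
  thr <- qt(1 - alpha / 2, df)
  res <- c(positive = 0, negative = 0)
  for (pol in c("positive", "negative")) {
    mask <- if (pol == "positive") tmap > thr else tmap < -thr
    if (!any(mask)) next
    mask <- .prune_neighbors(mask, adj_mat, min_nb)
    if (!any(mask)) next
    best <- 0
    for (mem in .components(mask, adj)) {
      mass <- sum(abs(tmap[cbind(mem[, 1], mem[, 2], mem[, 3])]))
      if (mass > best) best <- mass
    }
    res[pol] <- best
  }
  res
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Under the paired design the exchangeable units are subjects: each
#' permutation flips the sign of every subject's HA-minus-LA difference
#' independently, recomputes the t-map and re-clusters it with settings
#' identical to the observed analysis, and records the maximum cluster mass
#' per polarity (0 when no cluster forms). With `exhaustive = TRUE` all
#' `2^N` sign patterns are enumerated instead of sampled.
#'
#' @param ha,la subject-mean stacks as in [paired_t_map()].
#' @param n_perm number of random permutations (default 2000).
#' @param seed RNG seed for the sign flips.
#' @param exhaustive enumerate all `2^N` sign patterns (N <= 20).
#' @param alpha,graph,min_channel_neighbors as in [threshold_and_cluster()].
#' @return list with numeric vectors `positive` and `negative` of maximum
#'   cluster masses, plus `n_perm`.
#' @export
permutation_null <- function(ha, la, n_perm = 2000, seed = NULL,
                             exhaustive = FALSE, alpha = 0.01, graph,
                             min_channel_neighbors = 2) {
  if (!exhaustive && n_perm < 1) stop("n_perm must be at least 1")
  n <- dim(ha)[1]
  stopifnot(n >= 2)
  dm <- dim(ha)[-1]
  D <- matrix(ha - la, nrow = n)
  adj_mat <- attr(graph, "adjacency")
  adj <- lapply(seq_len(nrow(adj_mat)), function(i) which(adj_mat[i, ]))
  if (exhaustive) {
    stopifnot(n <= 20)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  np <- nrow(signs)
  # t-maps for all permutations from sufficient statistics:
  # sum(d_i^2) is sign-invariant, only the mean changes
  S2 <- colSums(D^2)
  M <- (signs %*% D) / n
  pos <- numeric(np); neg <- numeric(np)
  for (j in seq_len(np)) {
    m <- M[j, ]
    s2 <- (S2 - n * m^2) / (n - 1)
    s2[s2 < .Machine$double.eps * 100] <- Inf  # degenerate -> t = 0
    t <- m / sqrt(s2 / n)
    mm <- .max_masses(array(t, dm), n - 1, alpha, adj_mat, adj,
                      min_channel_neighbors)
    pos[j] <- mm["positive"]; neg[j] <- mm["negative"]
  }
  list(positive = pos, negative = neg, n_perm = np)
}

#' Attach permutation p-values to observed clusters
#'
#' `p = (1 + #\{null >= observed mass\}) / (1 + n_perm)` against the null of
#' the cluster's own polarity; the +1 tie-handling keeps p strictly
#' positive. Clusters are flagged significant when `p < cluster_alpha`
#' (default 0.025 per tail, i.e. a two-tailed familywise rate of 0.05 at
#' most, matching an elementwise two-tailed false-alarm level of 0.01
#' split over two tails at 0.025).
#'
#' @param clusters list from [threshold_and_cluster()].
#' @param null list from [permutation_null()].
#' @param cluster_alpha per-tail significance level (default 0.025).
#' @return the cluster list with `p_value` and `significant` fields added.
#' @export
cluster_p_values <- function(clusters, null, cluster_alpha = 0.025) {
  stopifnot(length(null$positive) > 0)
  lapply(clusters, function(cl) {
    nv <- null[[cl$polarity]]
    cl$p_value <- (1 + sum(nv >= cl$mass)) / (1 + length(nv))
    cl$significant <- cl$p_value < cluster_alpha
    cl
  })
}

#' Frequency/time bounds and channel set of a cluster
#'
#' The cluster's bounding intervals: min/max of its members' frequency and
#' time bins mapped to physical units, and the union of member channels.
#'
#' @param cluster an `ersp_cluster`.
#' @param freqs,times axis vectors (Hz, s).
#' @param channels channel names.
#' @return the cluster with `f_bounds`, `t_bounds`, `channel_set` added.
#' @export
extract_bounds <- function(cluster, freqs, times, channels) {
  stopifnot(nrow(cluster$members) >= 1)
  cluster$f_bounds <- range(freqs[cluster$members[, 2]])
  cluster$t_bounds <- range(times[cluster$members[, 3]])
  cluster$channel_set <- sort(unique(channels[cluster$members[, 1]]))
  cluster
}

#' Full cluster-based permutation contrast
#'
#' Convenience wrapper running the whole feature-extraction stage on
#' subject-mean ERSP stacks: restrict to the post-stimulus statistics
#' window, compute the paired t-map, threshold and cluster, build the
#' permutation null and attach p-values and bounds.
#'
#' @param ha,la subject x channel x frequency x time subject-mean stacks.
#' @param graph a [channel_neighbors()] graph.
#' @param alpha elementwise two-tailed threshold (default 0.01).
#' @param cluster_alpha per-tail cluster significance level (default 0.025).
#' @param n_perm permutations (default 2000).
#' @param min_channel_neighbors spatial-neighbour criterion (default 2).
#' @param seed permutation seed.
#' @param exhaustive enumerate all sign flips instead of sampling.
#' @param time_window statistics window in seconds (default `[0, 0.5]`).
#' @return a `cluster_result`: list with `clusters` (each carrying mass,
#'   p-value, significance flag, bounds, channel set), `tmap`, `null`,
#'   `freqs`, `times`, `channels`, `settings`.
#' @export
cluster_contrast <- function(ha, la, graph, alpha = 0.01,
                             cluster_alpha = 0.025, n_perm = 2000,
                             min_channel_neighbors = 2, seed = NULL,
                             exhaustive = FALSE, time_window = c(0, 0.5)) {
  times <- attr(ha, "times")
  freqs <- attr(ha, "freqs")
  channels <- attr(ha, "channels")
  keep <- which(times >= time_window[1] - .bin_eps &
                  times <= time_window[2] + .bin_eps)
  ha_w <- ha[, , , keep, drop = FALSE]
  la_w <- la[, , , keep, drop = FALSE]
  for (a in c("freqs", "channels")) {
    attr(ha_w, a) <- attr(ha, a); attr(la_w, a) <- attr(la, a)
  }
  attr(ha_w, "times") <- attr(la_w, "times") <- times[keep]
  tmap <- paired_t_map(ha_w, la_w)
  cl <- threshold_and_cluster(tmap, df = attr(tmap, "df"), alpha = alpha,
                              graph = graph,
                              min_channel_neighbors = min_channel_neighbors)
  null <- permutation_null(ha_w, la_w, n_perm = n_perm, seed = seed,
                           exhaustive = exhaustive, alpha = alpha,
                           graph = graph,
                           min_channel_neighbors = min_channel_neighbors)
  cl <- cluster_p_values(cl, null, cluster_alpha = cluster_alpha)
  cl <- lapply(cl, extract_bounds, freqs = freqs, times = times[keep],
               channels = channels)
  structure(list(clusters = cl, tmap = tmap, null = null,
                 freqs = freqs, times = times[keep], channels = channels,
                 settings = list(alpha = alpha, cluster_alpha = cluster_alpha,
                                 n_perm = null$n_perm,
                                 min_channel_neighbors = min_channel_neighbors,
                                 seed = seed, exhaustive = exhaustive,
                                 time_window = time_window)),
            class = "cluster_result")
}

#' Significant clusters of a contrast
#' @param result a `cluster_result`.
#' @return list of clusters with `significant = TRUE`.
#' @export
significant_clusters <- function(result) {
  Filter(function(cl) isTRUE(cl$significant), result$clusters)
}

#' Write a cluster report
#'
#' JSON carries bounds, mass, p-value and channels per cluster; the TSV is
#' a flat table of `cluster_id, polarity, f1, f2, t1, t2, p, significant`.
#'
#' @param result a `cluster_result`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the report as a list.
#' @export
write_cluster_report <- function(result, json_path = NULL, tsv_path = NULL) {
  rows <- lapply(seq_along(result$clusters), function(i) {
    cl <- result$clusters[[i]]
    list(cluster_id = i, polarity = cl$polarity, mass = cl$mass,
         p_value = cl$p_value, significant = cl$significant,
         f1 = cl$f_bounds[1], f2 = cl$f_bounds[2],
         t1 = cl$t_bounds[1], t2 = cl$t_bounds[2],
         n_triplets = nrow(cl$members), channels = cl$channel_set)
  })
  if (!is.null(json_path))
    jsonlite::write_json(list(settings = result$settings, clusters = rows),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    tab <- do.call(rbind, lapply(rows, function(r)
      data.frame(r[c("cluster_id", "polarity", "f1", "f2", "t1", "t2",
                     "p_value", "significant")])))
    if (is.null(tab)) tab <- data.frame(cluster_id = integer(0))
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(rows)
}
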