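# Scalp topogram rendering: collapse per-trial ERSP over a cluster's
# time-frequency box to one scalar per channel, interpolate the 31 channel
# values over the projected head disc with a thin-plate spline, and rescale
# to the CNN input size.
#
# Thin-plate interpolation is linear in the channel values, so the whole
# renderer reduces to one precomputed (pixels x channels) operator; it is
# exact at the electrode positions and smooth in between.

#' Average per-trial ERSP over a cluster's time-frequency box
#'
#' For every channel (not only the cluster's members), the mean ERSP over
#' the cluster's `[f1, f2] x [t1, t2]` box. This is the per-trial scalar
#' field that the scalp topogram renders.
#'
#' @param ersp a trial-level `ersp_array` (trial x channel x frequency x
#'   time) or a single channel x frequency x time array.
#' @param f_bounds,t_bounds cluster bounds in Hz / seconds; alternatively
#'   pass a cluster via `cluster`.
#' @param cluster an `ersp_cluster` carrying `f_bounds`/`t_bounds`.
#' @return trials x channels matrix (or a channel vector for 3-D input).
#' @export
cluster_average <- function(ersp, f_bounds = cluster$f_bounds,
                            t_bounds = cluster$t_bounds, cluster = NULL) {
  freqs <- attr(ersp, "freqs"); times <- attr(ersp, "times")
  fi <- which(freqs >= f_bounds[1] - .bin_eps & freqs <= f_bounds[2] + .bin_eps)
  ti <- which(times >= t_bounds[1] - .bin_eps & times <= t_bounds[2] + .bin_eps)
  if (length(fi) == 0 || length(ti) == 0)
    stop("degenerate cluster box: no frequency/time bins inside bounds")
  x <- unclass(ersp)
  if (length(dim(x)) == 3) {
    apply(x[, fi, ti, drop = FALSE], 1, mean)
  } else {
    apply(x[, , fi, ti, drop = FALSE], c(1, 2), mean)
  }
}

#' Precompute a thin-plate-spline scalp interpolator
#'
#' Builds the linear operator mapping per-channel values to a
#' `grid x grid` image over the unit head disc. Thin-plate radial basis
#' `U(r) = r^2 log r` with affine terms; interpolation is exact at the
#' electrode coordinates; pixels outside the head disc are masked.
#'
#' @param m a [montage()].
#' @param grid output grid size per side (default 64).
#' @return a `topo_interpolator` with fields `A` (pixels x channels
#'   operator), `mask` (inside-disc logical), `grid`, `channels`,
#'   `montage_hash`.
#' @export
topo_interpolator <- function(m, grid = 64) {
  stopifnot(inherits(m, "montage"), grid >= 8)
  xy <- as.matrix(m[, c("x", "y")])
  n <- nrow(xy)
  U <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  K <- U(as.matrix(stats::dist(xy)))
  P <- cbind(1, xy)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Minv <- solve(M)
  ax <- seq(-1, 1, length.out = grid)
  px <- as.matrix(expand.grid(x = ax, y = ax))
  d <- sqrt(outer(px[, 1], xy[, 1], `-`)^2 + outer(px[, 2], xy[, 2], `-`)^2)
  B <- cbind(U(d), 1, px)
  A <- B %*% Minv[, seq_len(n), drop = FALSE]
  mask <- rowSums(px^2) <= 1 + 1e-9
  structure(list(A = A, mask = mask, grid = grid, channels = m$name,
                 montage_hash = paste(m$name, round(m$x, 6), round(m$y, 6),
                                      collapse = ";")),
            class = "topo_interpolator")
}

#' Render one scalp topogram
#'
#' Interpolates a per-channel scalar field over the head disc. With
#' `color_limits` the image is clipped to the limits and scaled to
#' `[0, 1]` (limits must be fixed across trials of a run so that the CNN
#' sees comparable intensities); without, raw interpolated values are
#' returned. Pixels outside the head disc are set to `background`.
#'
#' @param values per-channel vector matching the interpolator's channels.
#' @param interp a [topo_interpolator()].
#' @param color_limits `c(lo, hi)` intensity limits, or `NULL` for raw
#'   values.
#' @param background value outside the head disc (default 0; `NA` gives a
#'   transparent border for plotting).
#' @return `grid x grid` numeric matrix with attribute `render_meta`
#'   (`color_limits`, `grid`, `montage_hash`).
#' @export
render_topogram <- function(values, interp, color_limits = NULL,
                            background = 0) {
  stopifnot(inherits(interp, "topo_interpolator"),
            length(values) == length(interp$channels))
  if (!is.null(color_limits) && any(!is.finite(color_limits)))
    stop("color limits must be finite")
  v <- as.vector(interp$A %*% values)
  if (!is.null(color_limits)) {
    v <- pmin(pmax(v, color_limits[1]), color_limits[2])
    v <- (v - color_limits[1]) / diff(color_limits)
  }
  v[!interp$mask] <- background
  img <- matrix(v, interp$grid, interp$grid)
  attr(img, "render_meta") <- list(color_limits = color_limits,
                                   grid = interp$grid,
                                   montage_hash = interp$montage_hash)
  img
}

#' Bilinear image rescale
#'
#' @param img numeric matrix.
#' @param target output side length (default 224); identity when the input
#'   is already that size.
#' @return `target x target` matrix; `render_meta` is carried over.
#' @export
rescale_image <- function(img, target = 224) {
  stopifnot(nrow(img) >= 8, ncol(img) >= 8)
  meta <- attr(img, "render_meta")
  if (nrow(img) == target && ncol(img) == target) return(img)
  out <- EBImage::resize(EBImage::Image(img), w = target, h = target)
  out <- matrix(EBImage::imageData(out), target, target)
  attr(out, "render_meta") <- meta
  out
}

#' Symmetric global colour limits for a topogram run
#'
#' `c(-q, q)` with `q` the `prob` quantile of the pooled absolute
#' cluster-averaged ERSP; computed once over the training subjects and
#' fixed thereafter so that image intensity stays class-informative.
#'
#' @param values numeric data (pooled cluster-averaged channel values).
#' @param prob quantile of `|values|` (default 0.98).
#' @return `c(lo, hi)`.
#' @export
compute_color_limits <- function(values, prob = 0.98) {
  q <- stats::quantile(abs(unlist(values)), prob, names = FALSE)
  if (q <= 0) q <- 1
  c(-q, q)
}

#' Build one subject's topogram stack
#'
#' One image per (trial, cluster): the cluster-averaged channel values of
#' every trial rendered as scalp maps under shared colour limits, rescaled
#' to the CNN input size.
#'
#' @param values_by_cluster list over clusters of trials x channels
#'   matrices (from [cluster_average()]).
#' @param labels per-trial class labels (`"LA"`/`"HA"`).
#' @param interp a [topo_interpolator()].
#' @param color_limits shared intensity limits (see
#'   [compute_color_limits()]).
#' @param size final image side (default the interpolator grid; use 224
#'   for the full-scale emulation).
#' @param subject_id subject identifier stored in the stack.
#' @return a `topogram_stack`: `images` (trial x cluster x size x size),
#'   `labels`, `subject_id`, `trial_ids`, `render_meta`.
#' @export
build_topogram_stack <- function(values_by_cluster, labels, interp,
                                 color_limits, size = NULL, subject_id = NA) {
  stopifnot(length(values_by_cluster) >= 1)
  ntrial <- nrow(values_by_cluster[[1]])
  stopifnot(length(labels) == ntrial)
  size <- size %||% interp$grid
  ncl <- length(values_by_cluster)
  images <- array(NA_real_, dim = c(ntrial, ncl, size, size))
  meta <- NULL
  for (ci in seq_len(ncl)) {
    vals <- values_by_cluster[[ci]]
    stopifnot(nrow(vals) == ntrial)
    for (tr in seq_len(ntrial)) {
      img <- render_topogram(vals[tr, ], interp, color_limits = color_limits)
      if (is.null(meta)) meta <- attr(img, "render_meta")
      images[tr, ci, , ] <- rescale_image(img, size)
    }
  }
  structure(list(images = images, labels = labels, subject_id = subject_id,
                 trial_ids = seq_len(ntrial), render_meta = meta),
            class = "topogram_stack")
}

#' Number of images in a stack
#' @param stack a `topogram_stack`.
#' @return integer count (trials x clusters).
#' @export
stack_size <- function(stack) {
  prod(dim(stack$images)[1:2])
}

#' Export a topogram stack as PNG files
#'
#' One greyscale file per (trial, cluster), named
#' `s<subject>_t<trial>_c<cluster>_<label>.png`.
#'
#' @param stack a `topogram_stack` built with colour limits (values in
#'   `[0, 1]`).
#' @param dir output directory (created if missing).
#' @return invisibly, the written file names.
#' @export
write_topogram_png <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(stack$images)
  files <- character(0)
  for (tr in seq_len(dm[1])) {
    for (ci in seq_len(dm[2])) {
      fn <- file.path(dir, sprintf("s%s_t%d_c%d_%s.png", stack$subject_id,
                                   tr, ci, stack$labels[tr]))
      img <- pmin(pmax(stack$images[tr, ci, , ], 0), 1)
      png::writePNG(img, fn)
      files <- c(files, fn)
    }
  }
  invisible(files)
}
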