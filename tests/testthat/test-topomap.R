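# Cluster-box averaging, scalp interpolation, rescaling, stacks.

test_that("the shipped montage round-trips through CSV and has sane geometry", {
  path <- system.file("extdata", "montage31.csv", package = "erspcluster")
  m <- read_montage(path)
  expect_s3_class(m, "montage")
  expect_equal(nrow(m), 31)
  expect_equal(as.data.frame(m), as.data.frame(default_montage()),
               tolerance = 1e-12)
  expect_true(all(m$x^2 + m$y^2 <= 1 + 1e-9))   # inside the head disc
  g <- channel_neighbors(m)
  deg <- lengths(g)
  expect_true(all(deg >= 1))
  expect_true(median(deg) >= 4 && median(deg) <= 6)
  # symmetry and irreflexivity
  adj <- attr(g, "adjacency")
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj) == FALSE))
  rt <- tempfile(fileext = ".csv")
  write_montage(m, rt)
  expect_equal(as.data.frame(read_montage(rt)), as.data.frame(m))
})

test_that("cluster averaging collapses the time-frequency box for every channel", {
  freqs <- 4:9; times <- seq(0, 0.45, 0.05)
  arr <- array(2.5, c(3, 6, 10))        # constant ERSP
  er <- structure(arr, freqs = freqs, times = times, channels = letters[1:3])
  v <- cluster_average(er, f_bounds = c(5, 7), t_bounds = c(0.1, 0.3))
  expect_equal(v, rep(2.5, 3))          # every channel, not only members
  # single-bin box returns that bin's slice
  arr2 <- array(seq_len(3 * 6 * 10), c(3, 6, 10))
  er2 <- structure(arr2, freqs = freqs, times = times, channels = letters[1:3])
  v2 <- cluster_average(er2, f_bounds = c(6, 6), t_bounds = c(0.2, 0.2))
  expect_equal(v2, arr2[, 3, 5])
  # checkerboard +/-1 with even bin counts averages to zero
  cb <- array(0, c(1, 6, 10))
  cb[1, , ] <- outer((-1)^(1:6), (-1)^(1:10))
  er3 <- structure(cb, freqs = freqs, times = times, channels = "a")
  expect_equal(cluster_average(er3, c(4, 7), c(0, 0.15)), 0)
  # trial-level input gives a trials x channels matrix
  tr <- array(1, c(5, 3, 6, 10))
  er4 <- structure(tr, freqs = freqs, times = times, channels = letters[1:3])
  expect_equal(dim(cluster_average(er4, c(5, 7), c(0.1, 0.3))), c(5, 3))
  expect_error(cluster_average(er, f_bounds = c(50, 60), t_bounds = c(0, 0.1)),
               "degenerate")
})

test_that("thin-plate rendering is exact at electrodes and uniform for uniform input", {
  m <- default_montage()
  ip <- topo_interpolator(m, grid = 48)
  img <- render_topogram(rep(3, 31), ip, background = NA)
  expect_equal(range(img, na.rm = TRUE), c(3, 3), tolerance = 1e-9)
  # one-hot field peaks at that electrode's pixel
  oh <- rep(0, 31); oh[which(m$name == "Fz")] <- 1
  img2 <- render_topogram(oh, ip, background = NA)
  ax <- seq(-1, 1, length.out = 48)
  pk <- which(img2 == max(img2, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(abs(ax[pk[1]] - m$x[m$name == "Fz"]), 2 / 47)
  expect_lt(abs(ax[pk[2]] - m$y[m$name == "Fz"]), 2 / 47)
  # rotating the montage by a full turn leaves the image unchanged
  m2 <- m
  th <- 2 * pi
  m2$x <- cos(th) * m$x - sin(th) * m$y
  m2$y <- sin(th) * m$x + cos(th) * m$y
  ip2 <- topo_interpolator(montage(as.data.frame(m2)), grid = 48)
  set.seed(2); v <- rnorm(31)
  expect_equal(render_topogram(v, ip2), render_topogram(v, ip),
               tolerance = 1e-6)
  # duplicate coordinates are refused
  bad <- as.data.frame(m); bad$x[2] <- bad$x[1]; bad$y[2] <- bad$y[1]
  expect_error(montage(bad), "duplicate electrode")
})

test_that("colour limits clip and scale to [0,1] with background 0", {
  ip <- topo_interpolator(default_montage(), grid = 32)
  img <- render_topogram(rep(0.5, 31), ip, color_limits = c(-1, 1))
  inside <- matrix(ip$mask, 32, 32)
  expect_equal(unique(round(img[inside], 9)), 0.75)
  expect_true(all(img[!inside] == 0))
  expect_error(render_topogram(rep(1, 31), ip, color_limits = c(0, Inf)),
               "finite")
  lims <- compute_color_limits(c(-0.2, 0.1, 2))
  expect_equal(lims[1], -lims[2])
})

test_that("bilinear rescale preserves constants, identity, and peak locations", {
  ip <- topo_interpolator(default_montage(), grid = 64)
  img <- render_topogram(rep(2, 31), ip, background = 2)
  expect_identical(rescale_image(img, 64), img)             # identity
  out <- rescale_image(img, 224)
  expect_equal(dim(out), c(224, 224))
  expect_equal(range(out), c(2, 2), tolerance = 1e-9)       # constant stays
  # one-hot peak moves to the mapped pixel within one source pixel
  hot <- matrix(0, 64, 64); hot[20, 41] <- 1
  up <- rescale_image(hot, 224)
  pk <- which(up == max(up), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[1] / (224 / 64) - 20), 1 + 224 / 64)
  expect_lt(abs(pk[2] / (224 / 64) - 41), 1 + 224 / 64)
})

test_that("stacks conserve image counts and share fixed colour limits", {
  labels <- rep(c("LA", "HA"), each = 10)
  stacks <- label_only_stacks(3, labels, n_clusters = 3, grid = 12)
  expect_equal(vapply(stacks, stack_size, numeric(1)), rep(60, 3))
  expect_equal(dim(stacks[[1]]$images), c(20, 3, 12, 12))
  metas <- lapply(stacks, function(s) s$render_meta$color_limits)
  expect_true(all(vapply(metas, identical, logical(1), metas[[1]])))
  expect_true(all(vapply(stacks, function(s)
    identical(s$render_meta$montage_hash, stacks[[1]]$render_meta$montage_hash),
    logical(1))))
})

test_that("interpolation is monotone in a channel's neighbourhood", {
  m <- default_montage()
  ip <- topo_interpolator(m, grid = 48)
  set.seed(5)
  v <- rnorm(31)
  i_cz <- which(m$name == "Cz")
  img_lo <- render_topogram(v, ip, background = NA)
  v2 <- v; v2[i_cz] <- v[i_cz] + 1
  img_hi <- render_topogram(v2, ip, background = NA)
  ax <- seq(-1, 1, length.out = 48)
  near <- outer(ax - m$x[i_cz], ax * 0, `+`)^2 +
    outer(ax * 0, ax - m$y[i_cz], `+`)^2 < 0.15^2
  diffs <- (img_hi - img_lo)[near]
  expect_true(all(diffs[!is.na(diffs)] > 0))
})

test_that("PNG export writes one named file per trial and cluster", {
  skip_if_not_installed("png")
  labels <- c("LA", "HA")
  stacks <- label_only_stacks(1, labels, n_clusters = 2, grid = 12)
  dir <- tempfile("pngs")
  files <- write_topogram_png(stacks[[1]], dir)
  expect_length(files, 4)
  expect_true(all(file.exists(files)))
  expect_true(any(grepl("s1_t1_c1_LA\\.png$", files)))
  expect_true(any(grepl("s1_t2_c2_HA\\.png$", files)))
})
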