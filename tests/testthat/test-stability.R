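# Delta metrics, leave-one-out bound re-extraction, accuracy regression.

test_that("delta metrics match hand-computed values exactly", {
  expect_equal(delta_f(c(7.25, 8.5), c(7.25, 8.5)), 0)
  expect_equal(delta_f(c(7.25, 8.5), c(7.45, 8.3)), 16, tolerance = 1e-12)
  expect_equal(delta_f(c(20, 24), c(22, 26)), 50, tolerance = 1e-12)
  expect_equal(delta_t(c(0.02, 0.2), c(0.02, 0.2)), 0)
  expect_equal(delta_t(c(0.02, 0.2), c(0.04, 0.15)), 700 / 36,
               tolerance = 1e-12)
  # interval shifted wholly by the common width -> 100%
  expect_equal(delta_t(c(0.1, 0.3), c(0.3, 0.5)), 100, tolerance = 1e-12)
  expect_error(delta_f(c(8, 8), c(7, 9)), "zero-width")
  expect_error(delta_t(c(0.2, 0.2), c(0.1, 0.3)), "zero-width")
})

test_that("delta metrics are scale-covariant and zero iff intervals coincide", {
  set.seed(6)
  for (i in 1:20) {
    com <- sort(runif(2, 0, 10)); ind <- sort(runif(2, 0, 10))
    if (diff(com) < 1e-3) next
    d <- delta_f(com, ind)
    expect_gte(d, 0)
    # measuring in other units (kHz, ms) leaves the percent unchanged
    expect_equal(delta_f(com / 1000, ind / 1000), d, tolerance = 1e-9)
    expect_equal(delta_f(com * 1000, ind * 1000), d, tolerance = 1e-9)
    if (d == 0) expect_equal(com, ind)
    if (all(com == ind)) expect_equal(d, 0)
  }
})

test_that("leave-one-out bounds are deterministic and overlap the common run", {
  eff <- list(effect_spec(c("P3", "Pz", "P4", "O1", "Oz", "O2"),
                          8, 16, 0.05, 0.4, 3,
                          jitter = list(f_sd = 0.25, t_sd = 0.01,
                                        gain_sd = 0.1)))
  st <- reduced_study(6, 15, eff, seed = 41)
  g <- channel_neighbors(default_montage())
  settings <- list(n_perm = 100, seed = 7)
  common <- do.call(cluster_contrast,
                    c(list(ha = st$ha, la = st$la, graph = g), settings))
  expect_gte(length(significant_clusters(common)), 1)
  rec <- loso_cluster_bounds(st$ha, st$la, excluded = 3, g, settings,
                             common = common)
  expect_equal(nrow(rec), length(significant_clusters(common)))
  # high-gain effect: the matched cluster overlaps the common bounds
  expect_true(rec$present[1])
  expect_gt(jaccard(c(rec$f1_ind[1], rec$f2_ind[1]),
                    significant_clusters(common)[[1]]$f_bounds), 0)
  expect_gt(jaccard(c(rec$t1_ind[1], rec$t2_ind[1]),
                    significant_clusters(common)[[1]]$t_bounds), 0)
  expect_gte(rec$delta_f[1], 0)
  # determinism of repeated runs
  rec2 <- loso_cluster_bounds(st$ha, st$la, excluded = 3, g, settings,
                              common = common)
  expect_identical(rec, rec2)
  # excluding then re-adding the subject reproduces the common bounds:
  # run the "leave-one-out" on an augmented stack whose extra subject is
  # dropped, leaving exactly the original subjects
  aug_ha <- subject_mean_stack(c(
    lapply(seq_len(6), function(k) {
      a <- st$ha[k, , , ]
      structure(a, freqs = attr(st$ha, "freqs"), times = attr(st$ha, "times"),
                channels = attr(st$ha, "channels"))
    }),
    list(structure(st$ha[1, , , ], freqs = attr(st$ha, "freqs"),
                   times = attr(st$ha, "times"),
                   channels = attr(st$ha, "channels")))))
  aug_la <- subject_mean_stack(c(
    lapply(seq_len(6), function(k) {
      a <- st$la[k, , , ]
      structure(a, freqs = attr(st$la, "freqs"), times = attr(st$la, "times"),
                channels = attr(st$la, "channels"))
    }),
    list(structure(st$la[1, , , ], freqs = attr(st$la, "freqs"),
                   times = attr(st$la, "times"),
                   channels = attr(st$la, "channels")))))
  rec3 <- loso_cluster_bounds(aug_ha, aug_la, excluded = 7, g, settings,
                              common = common)
  com_cl <- significant_clusters(common)[[1]]
  expect_equal(c(rec3$f1_ind[1], rec3$f2_ind[1]), com_cl$f_bounds)
  expect_equal(c(rec3$t1_ind[1], rec3$t2_ind[1]), com_cl$t_bounds)
  expect_equal(rec3$delta_f[1], 0)
  expect_equal(rec3$delta_t[1], 0)
})

test_that("stability records flag absent clusters instead of imputing", {
  # null data: typically no clusters in either run; absent matches are NA
  eff <- list(effect_spec("Fz", 7, 9, 0, 0.15, 1))
  st <- reduced_study(5, 4, eff, seed = 13, freqs = seq(6, 18, 4),
                      times = seq(-0.5, 0.4, 0.1))
  g <- channel_neighbors(default_montage())
  res <- stability_analysis(st$ha, st$la, g, list(n_perm = 40, seed = 3))
  expect_true(is.null(res$records) ||
                all(is.na(res$records$delta_f[!res$records$present])))
})

test_that("accuracy regression recovers exact and noisy linear structure", {
  # exact linear fixture: y = 0.8 - 0.01 x, zero noise
  x <- c(1, 3, 5, 8, 13, 21)
  y <- 0.8 - 0.01 * x
  r <- suppressWarnings(accuracy_regression(y, data.frame(delta_t_1 = x)))
  expect_equal(unname(r$coefficients), c(0.8, -0.01), tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  # rank errors
  expect_error(accuracy_regression(y, data.frame(a = rep(2, 6))),
               "zero-variance")
  expect_error(accuracy_regression(y[1:3],
                                   data.frame(a = x[1:3], b = x[1:3]^2)),
               "rank error")
  # coefficient recovery within the CI at the study's n = 16
  set.seed(99)
  n <- 16
  X <- data.frame(d1 = runif(n, 0, 30), d2 = runif(n, 0, 30),
                  d3 = runif(n, 0, 30))
  beta <- c(-0.004, -0.002, 0)
  yy <- 0.75 + as.matrix(X) %*% beta + rnorm(n, sd = 0.01)
  rr <- accuracy_regression(as.vector(yy), X)
  fit <- lm(yy ~ d1 + d2 + d3, data = X)   # oracle
  ci <- confint(fit)
  expect_true(all(beta >= ci[-1, 1] & beta <= ci[-1, 2]))
  expect_equal(unname(rr$coefficients), unname(coef(fit)), tolerance = 1e-10)
  expect_equal(rr$n, 16)
  # complete cases only: a missing cluster drops the subject
  X$d2[3] <- NA
  rr2 <- accuracy_regression(as.vector(yy), X)
  expect_equal(rr2$n, 15)
})
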