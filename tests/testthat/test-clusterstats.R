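# Paired t-map, clustering, permutation null and p-values.

test_that("paired t matches the hand formula and t.test, and is antisymmetric", {
  ha <- array(c(2, 0, 1, 1), c(4, 1, 1, 1))
  la <- array(0, c(4, 1, 1, 1))
  tm <- paired_t_map(ha, la)
  expect_equal(tm[1, 1, 1], sqrt(6), tolerance = 1e-12)
  expect_equal(attr(tm, "df"), 3)
  # independent oracle
  expect_equal(tm[1, 1, 1],
               unname(t.test(c(2, 0, 1, 1), rep(0, 4), paired = TRUE)$statistic))
  # antisymmetry under class swap
  set.seed(1)
  a <- array(rnorm(5 * 2 * 3 * 4), c(5, 2, 3, 4))
  b <- array(rnorm(5 * 2 * 3 * 4), c(5, 2, 3, 4))
  expect_equal(unclass(paired_t_map(a, b)), -unclass(paired_t_map(b, a)))
  # zero-variance triplet -> 0 with a warning
  expect_warning(tz <- paired_t_map(array(1, c(3, 1, 1, 1)),
                                    array(0, c(3, 1, 1, 1))),
                 "zero difference variance")
  expect_equal(tz[1, 1, 1], 0)
})

test_that("null data give a near-zero-mean t-map", {
  set.seed(7)
  a <- array(rnorm(40 * 4 * 5 * 5), c(40, 4, 5, 5))
  b <- array(rnorm(40 * 4 * 5 * 5), c(40, 4, 5, 5))
  tm <- paired_t_map(a, b)
  expect_lt(abs(mean(tm)), 0.15)
})

test_that("thresholding and clustering match brute-force components on a toy grid", {
  g <- channel_neighbors(toy_montage(), 0.5)
  tmap <- structure(array(0, c(2, 3, 3)), df = 60)
  expect_length(threshold_and_cluster(tmap, graph = g), 0)   # all subthreshold
  # single suprathreshold triplet with the neighbour rule disabled
  # (threshold at df = 60 is qt(0.995, 60) ~ 2.66)
  tmap[1, 2, 2] <- 3.2
  cl <- threshold_and_cluster(tmap, graph = g, min_channel_neighbors = 0)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 3.2)
  expect_equal(cl[[1]]$polarity, "positive")
  # a 2x2x2 suprathreshold block on the connected channel pair is one cluster
  tmap2 <- structure(array(0, c(2, 3, 3)), df = 9)
  tmap2[, 1:2, 1:2] <- 4
  cl2 <- threshold_and_cluster(tmap2, graph = g, min_channel_neighbors = 0)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$mass, 8 * 4)
  expect_equal(nrow(cl2[[1]]$members), 8)
  # brute-force oracle: repeated pairwise merging over the same mask
  brute <- function(mask_idx, adj) {
    comp <- seq_len(nrow(mask_idx))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(mask_idx))) for (j in seq_len(nrow(mask_idx))) {
        a <- mask_idx[i, ]; b <- mask_idx[j, ]
        conn <- (a[2] == b[2] && a[3] == b[3] && b[1] %in% adj[[a[1]]]) ||
          (a[1] == b[1] && a[3] == b[3] && abs(a[2] - b[2]) == 1) ||
          (a[1] == b[1] && a[2] == b[2] && abs(a[3] - b[3]) == 1)
        if (conn && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    length(unique(comp))
  }
  set.seed(4)
  for (rep in 1:5) {
    tmap3 <- structure(array(0, c(2, 3, 3)), df = 9)
    hot <- sample(18, 7)
    tmap3[hot] <- 5
    cl3 <- threshold_and_cluster(tmap3, graph = g, min_channel_neighbors = 0)
    idx <- which(unclass(tmap3) > 0, arr.ind = TRUE)
    expect_equal(length(cl3), brute(idx, list(2L, 1L)))
  }
})

test_that("the spatial-neighbour criterion prunes isolated triplets", {
  # 3 channels in a line: A-B, B-C adjacent; A-C not
  m <- montage(data.frame(name = c("A", "B", "C"), x = c(0, 0.3, 0.6), y = 0))
  g <- channel_neighbors(m, 0.4)
  tmap <- structure(array(0, c(3, 1, 1)), df = 9)
  tmap[, 1, 1] <- 5  # all three suprathreshold
  # B has 2 suprathreshold neighbours, A and C only 1 -> with min 2 only B
  cl <- threshold_and_cluster(tmap, graph = g, min_channel_neighbors = 2)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 1)
  expect_equal(cl[[1]]$members[1, "ch"], c(ch = 2))
  cl0 <- threshold_and_cluster(tmap, graph = g, min_channel_neighbors = 0)
  expect_equal(nrow(cl0[[1]]$members), 3)
})

test_that("permutation p-values follow the +1 counting rule", {
  cl <- list(structure(list(members = cbind(ch = 1, f = 1, t = 1),
                            polarity = "positive", mass = 10),
                       class = "ersp_cluster"))
  null <- list(positive = rep(1, 2000), negative = rep(1, 2000), n_perm = 2000)
  p <- cluster_p_values(cl, null)[[1]]$p_value
  expect_equal(p, 1 / 2001)      # observed beats every null value
  null$positive <- rep(100, 2000)
  expect_equal(cluster_p_values(cl, null)[[1]]$p_value, 1)
  # observed equal to the null median -> p about 0.5
  null$positive <- seq_len(2000)
  cl[[1]]$mass <- 1000
  expect_equal(cluster_p_values(cl, null)[[1]]$p_value,
               (1 + 1001) / 2001)
})

test_that("bounds are member min/max mapped to axis units", {
  freqs <- 4:12; times <- seq(0, 0.45, 0.05); chs <- c("A", "B")
  cl <- structure(list(members = rbind(c(1, 4, 1), c(2, 6, 4)),
                       polarity = "positive", mass = 5),
                  class = "ersp_cluster")
  colnames(cl$members) <- c("ch", "f", "t")
  b <- extract_bounds(cl, freqs, times, chs)
  expect_equal(b$f_bounds, c(7, 9))
  expect_equal(b$t_bounds, c(0, 0.15))
  expect_equal(b$channel_set, c("A", "B"))
  # singleton member -> degenerate bounds
  cl$members <- cl$members[1, , drop = FALSE]
  b1 <- extract_bounds(cl, freqs, times, chs)
  expect_equal(b1$f_bounds, c(7, 7))
  expect_equal(b1$t_bounds, c(0, 0))
})

test_that("relabelling HA<->LA maps clusters to opposite polarity with equal mass", {
  eff <- list(effect_spec(c("P3", "Pz", "P4", "O1", "Oz", "O2"),
                          8, 16, 0.05, 0.4, 3))
  st <- reduced_study(6, 10, eff, seed = 21)
  g <- channel_neighbors(default_montage())
  r1 <- cluster_contrast(st$ha, st$la, graph = g, n_perm = 50, seed = 2)
  r2 <- cluster_contrast(st$la, st$ha, graph = g, n_perm = 50, seed = 2)
  expect_gt(length(r1$clusters), 0)
  m1 <- sort(vapply(r1$clusters, `[[`, numeric(1), "mass"))
  m2 <- sort(vapply(r2$clusters, `[[`, numeric(1), "mass"))
  expect_equal(m1, m2)
  p1 <- table(vapply(r1$clusters, `[[`, character(1), "polarity"))
  p2 <- table(vapply(r2$clusters, `[[`, character(1), "polarity"))
  expect_equal(unname(p1["positive"]), unname(p2["negative"]))
  # observed masses do not depend on the permutation seed
  r3 <- cluster_contrast(st$ha, st$la, graph = g, n_perm = 50, seed = 99)
  expect_equal(sort(vapply(r3$clusters, `[[`, numeric(1), "mass")), m1)
})

test_that("exhaustive enumeration covers all sign patterns and MC converges to it", {
  eff <- list(effect_spec(c("P3", "Pz", "P4", "O1", "Oz", "O2"),
                          8, 16, 0.05, 0.4, 2.5))
  st <- reduced_study(5, 10, eff, seed = 33, freqs = seq(6, 18, 2),
                      times = seq(-0.5, 0.4, 0.1))
  g <- channel_neighbors(default_montage())
  ex <- permutation_null(st$ha, st$la, exhaustive = TRUE, graph = g)
  expect_equal(ex$n_perm, 32)
  mc <- permutation_null(st$ha, st$la, n_perm = 400, seed = 8, graph = g)
  # identity flips are included, so the observed statistic appears in its
  # own exhaustive null and p can never be exactly 0
  tm <- paired_t_map(st$ha, st$la)
  obs <- threshold_and_cluster(tm, graph = g)
  if (length(obs) > 0) {
    p_ex <- (1 + sum(ex$positive >= obs[[1]]$mass)) / (1 + 32)
    expect_gt(p_ex, 0)
    p_mc <- (1 + sum(mc$positive >= obs[[1]]$mass)) / (1 + 400)
    q <- sum(ex$positive >= obs[[1]]$mass) / 32
    expect_lt(abs(p_mc - q), 3 * sqrt(q * (1 - q) / 400) + 2 / 401)
  }
  expect_error(permutation_null(st$ha, st$la, n_perm = 0, graph = g),
               "at least 1")
})

test_that("cluster reports serialize to JSON and TSV", {
  eff <- list(effect_spec(c("P3", "Pz", "P4", "O1", "Oz", "O2"),
                          8, 16, 0.05, 0.4, 3))
  st <- reduced_study(6, 10, eff, seed = 21)
  g <- channel_neighbors(default_montage())
  res <- cluster_contrast(st$ha, st$la, graph = g, n_perm = 50, seed = 2)
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_cluster_report(res, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_equal(length(j$clusters), length(res$clusters))
  tab <- read.delim(tf)
  expect_equal(nrow(tab), length(res$clusters))
  expect_true(all(c("f1", "f2", "t1", "t2", "p_value") %in% names(tab)))
})
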