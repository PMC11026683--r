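# CAP extraction: thresholding, correlation-distance K-means++, explained
# variance, elbow selection, maps and anti-pair ordering

test_that("rank-based thresholding keeps the stated extremes", {
  v <- 1:100
  out <- threshold_frame(v, 10, 5)
  expect_equal(sort(which(out != 0)), c(1:5, 91:100))   # 15 survivors
  expect_equal(out[out != 0], c(1:5, 91:100))
  # negation swaps survivors through the 10 vs 5 asymmetry
  out_neg <- threshold_frame(-v, 10, 5)
  expect_equal(sort(which(out_neg != 0)), c(1:10, 96:100))
  # degenerate all-equal frame zeroes out and is flagged
  z <- threshold_frame(rep(0, 100))
  expect_true(all(z == 0))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(threshold_frame(1:10), "m < 20")
  x <- cbind(as.numeric(1:100), rep(0, 100))
  expect_message(xt <- threshold_frames(x), "degenerate")
  expect_equal(attr(xt, "degenerate_frames"), 2L)
})

test_that("perfectly separable families are recovered exactly", {
  st <- fixture_states(n_states = 2, n_voxels = 100, seed = 3)
  # orthogonal-ish families: pattern 1 and an independent pattern
  p1 <- st$patterns[, 1]
  p2 <- with_seed(4, { v <- rnorm(100); v <- v - mean(v); v / sd(v) })
  x <- cbind(matrix(p1, 100, 10), matrix(p2, 100, 10))
  part <- cluster_frames(x, 2, seed = 1, n_restarts = 2)
  expect_lt(part$D, 1e-10)
  expect_length(unique(part$labels[1:10]), 1L)
  expect_length(unique(part$labels[11:20]), 1L)
  expect_true(part$labels[1] != part$labels[20])
  # K = 1: single cluster, centroid along the global mean direction
  part1 <- cluster_frames(x, 1, seed = 1, n_restarts = 1)
  expect_true(all(part1$labels == 1))
  gm <- rowMeans(capdyn:::normalize_frames(x))
  expect_gt(abs(cor(part1$centroids[1, ], gm)), 1 - 1e-10)
  expect_error(cluster_frames(x[, 1:3], 5, 1), "smaller")
})

test_that("clustering matches the naive Lloyd oracle and the ground truth", {
  st <- fixture_states(n_states = 6, n_voxels = 120, seed = 5)
  truth <- with_seed(6, sample(c(1L, 3L, 5L), 60, replace = TRUE))
  x <- st$patterns[, truth] + with_seed(7, matrix(rnorm(120 * 60, 0, 0.3),
                                                  120, 60))
  xt <- threshold_frames(x)
  part <- cluster_frames(xt, 3, seed = 2, n_restarts = 5)
  # >= 95% agreement with the generating states after best matching
  tab <- table(part$labels, truth)
  expect_gte(sum(apply(tab, 1, max)) / 60, 0.95)
  # same initial centroids => same objective as the naive oracle
  # (one seed per true family, so neither path hits empty-cluster repair)
  yn <- capdyn:::normalize_frames(xt)
  init <- t(yn[, c(which(truth == 1)[1], which(truth == 3)[1],
                   which(truth == 5)[1])])
  fast <- cluster_frames(xt, 3, init = init)
  slow <- oracle_lloyd(xt, init)
  expect_equal(fast$D, slow$D, tolerance = 1e-8)
  expect_equal(fast$labels, slow$labels)
})

test_that("explained variance matches a brute-force transcription", {
  # 9 hand-written vectors in 3 clusters
  x <- cbind(c(1, 2, 3, 4, 2), c(1.1, 2, 3.2, 4, 2), c(0.9, 2.2, 3, 4.1, 2),
             c(4, 3, 2, 1, 3), c(4.2, 3, 1.8, 1, 3), c(4, 2.9, 2, 1.2, 3.1),
             c(1, -1, 2, -2, 0.5), c(1.2, -1, 2, -2.2, 0.4),
             c(1, -0.9, 2.1, -2, 0.5))
  part <- cluster_frames(x, 3, seed = 3, n_restarts = 5)
  ev <- explained_variance(part)
  oracle <- oracle_explained_variance(x, part$labels, part$centroids)
  expect_equal(ev$V_w, oracle$V_w, tolerance = 1e-12)
  expect_equal(ev$V_B, oracle$V_B, tolerance = 1e-12)
  expect_equal(ev$EV, oracle$EV, tolerance = 1e-12)
  expect_true(ev$EV >= 0 && ev$EV <= 1)
  # single cluster: V_B = 0, EV = 0
  p1 <- cluster_frames(x, 1, seed = 1, n_restarts = 1)
  ev1 <- explained_variance(p1)
  expect_equal(ev1$V_B, 0)
  expect_equal(ev1$EV, 0)
  # zero within-cluster spread: V_w = 0, EV = 1
  x0 <- cbind(x[, c(1, 1, 4, 4)])
  p0 <- cluster_frames(x0, 2, seed = 1, n_restarts = 3)
  ev0 <- explained_variance(p0)
  expect_equal(ev0$V_w, 0, tolerance = 1e-20)
  expect_equal(ev0$EV, 1)
})

test_that("the gain rule picks the stated elbow on a listed curve", {
  curve <- data.frame(K = 2:7, EV = c(0.30, 0.40, 0.48, 0.50, 0.501, 0.5012))
  curve$gain <- c(NA, diff(curve$EV) / head(curve$EV, -1))
  # smallest K whose subsequent gains all stay below 0.5%
  expect_equal(select_k_elbow(curve), 5)
  # alternative reading: first K whose own gain is below 0.5%
  expect_equal(select_k_elbow(curve, rule = "next_only"), 6)
  # strictly linear growth: no elbow, warning, max K returned
  lin <- data.frame(K = 2:8, EV = seq(0.3, by = 0.02, length.out = 7))
  lin$gain <- c(NA, diff(lin$EV) / head(lin$EV, -1))
  expect_warning(k <- select_k_elbow(lin), "no elbow")
  expect_equal(k, 8)
})

test_that("EV is non-decreasing in K for best-of-restarts partitions", {
  st <- fixture_states(n_states = 4, n_voxels = 100, seed = 8)
  truth <- with_seed(9, sample(4, 120, replace = TRUE))
  x <- st$patterns[, truth] + with_seed(10, matrix(rnorm(100 * 120, 0, 0.3),
                                                   100, 120))
  curve <- variance_curve(threshold_frames(x), 2:6, seed = 1, n_restarts = 5)
  expect_true(all(diff(curve$EV) > -1e-6))
})

test_that("CAP maps are exact in the noiseless limit and cell-consistent", {
  st <- fixture_states(n_states = 4, n_voxels = 100, seed = 12)
  co <- fixture_cohort(seed = 12, n_per_cell = 1, n_frames = 80,
                       noise_sd = 0, states = st)
  concat <- concat_frames(co$scans)
  xt <- threshold_frames(concat$x)
  part <- cluster_frames(xt, 4, seed = 1, n_restarts = 3)
  maps <- compute_cap_maps(part, concat)
  # noiseless: each map equals the planted pattern (amplitude 1) exactly
  matched <- match_maps_to_patterns(maps$cohort, st$patterns)
  expect_true(all(matched > 1 - 1e-10))
  # cohort map = frame-count weighted mean of cell maps
  for (k in 1:4) {
    w <- maps$cell_counts[k, ]
    cells <- vapply(names(co$scans), function(nm) NA, NA)
    stack <- do.call(rbind, lapply(maps$cells, function(m) m[k, ]))
    stack[is.na(stack)] <- 0
    expect_equal(drop(w %*% stack) / sum(w), maps$cohort[k, ],
                 tolerance = 1e-10)
  }
})

test_that("anti-pair ordering recovers exact pairs and flags odd K", {
  p <- with_seed(20, { v <- rnorm(80); v - mean(v) })
  q <- with_seed(21, { v <- rnorm(80); v <- v - mean(v)
    v - p * sum(v * p) / sum(p * p) })   # orthogonal to p
  maps <- structure(list(cohort = rbind(p, -p, q, -q),
                         cells = list(), cell_counts = matrix(0, 4, 0),
                         occurrence_pct = c(40, 10, 30, 20),
                         order = 1:4), class = "cap_map_set")
  out <- pair_and_order_caps(maps)
  expect_equal(lapply(out$pairs, sort), list(c(1L, 2L), c(3L, 4L)))
  expect_equal(out$pair_cor, c(-1, -1))
  # within-pair order: higher occurrence first
  expect_equal(out$order[1:2], c(1L, 2L))
  expect_equal(out$order[3:4], c(3L, 4L))
  # odd K: unpaired CAP flagged
  maps3 <- structure(list(cohort = rbind(p, -p, q), cells = list(),
                          cell_counts = matrix(0, 3, 0),
                          occurrence_pct = c(50, 30, 20), order = 1:3),
                     class = "cap_map_set")
  out3 <- pair_and_order_caps(maps3)
  expect_true(any(grepl("unpaired", out3$flags)))
  expect_equal(out3$order[3], 3L)
})

test_that("thresholded and unthresholded clustering give matching maps", {
  st <- fixture_states(n_states = 4, n_voxels = 100, seed = 14)
  co <- fixture_cohort(seed = 14, n_per_cell = 1, n_frames = 120,
                       noise_sd = 0.3, states = st)
  concat <- concat_frames(co$scans)
  xt <- threshold_frames(concat$x)
  part_t <- cluster_frames(xt, 4, seed = 2, n_restarts = 3)
  part_u <- cluster_frames(concat$x, 4, seed = 2, n_restarts = 3)
  maps_t <- compute_cap_maps(part_t, concat)$cohort
  maps_u <- compute_cap_maps(part_u, concat)$cohort
  cc <- cor(t(maps_t), t(maps_u))
  # after best matching, maps agree strongly (> 0.9)
  expect_true(all(apply(cc, 1, max) > 0.9))
})
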