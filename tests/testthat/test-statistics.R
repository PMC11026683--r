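# CAP statistics: T maps, two-way ANOVA with interaction dropping, FDR and
# cluster-extent correction, temporal metrics, repeated-measures ANOVA

test_that("one-sample T maps give the closed-form statistic", {
  frames <- rbind(c(1, 2, 3), c(0, 0, 0))
  tm <- suppressMessages(one_sample_t_map(frames))
  expect_equal(tm$t[1], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tm$df, 2L)
  expect_true(is.na(tm$t[2]))                # zero-variance voxel
  expect_false(tm$sig_pos[2] || tm$sig_neg[2])
  expect_error(one_sample_t_map(frames[, 1:2, drop = FALSE]), "3 frames")
})

test_that("a planted activation survives Bonferroni at the stated power", {
  # amplitude 1 voxel, noise 0.5, n = 150 frames, 500-voxel map
  x <- with_seed(31, matrix(rnorm(500 * 150, 0, 0.5), 500, 150))
  x[7, ] <- x[7, ] + 1
  tm <- one_sample_t_map(x)
  expect_true(tm$sig_pos[7])
  # and the null voxels stay mostly quiet under Bonferroni
  expect_lt(sum(tm$sig_pos | tm$sig_neg) - 1, 3)
})

test_that("vectorized two-way ANOVA agrees with per-voxel lm fits", {
  n_per <- 4
  genotype <- rep(c("WT", "TG"), each = 2 * n_per)
  age <- rep(rep(c("4M", "6M"), each = n_per), 2)
  y <- with_seed(32, matrix(rnorm(16 * 8), 16, 8))
  y[, 1] <- y[, 1] + (genotype == "TG") * 2          # genotype effect
  y[, 2] <- y[, 2] + (genotype == "TG") * (age == "6M") * 3  # interaction
  res <- voxelwise_two_way_anova(y, genotype, age)
  for (v in 1:8) {
    df <- data.frame(y = y[, v], g = factor(genotype), a = factor(age))
    p_int <- stats::anova(stats::lm(y ~ g * a, df))["g:a", "Pr(>F)"]
    expect_equal(res$p_interaction[v], p_int, tolerance = 1e-10)
    if (p_int > 0.05) {
      p_g <- stats::anova(stats::lm(y ~ a + g, df))["g", "Pr(>F)"]
      p_a <- stats::anova(stats::lm(y ~ g + a, df))["a", "Pr(>F)"]
      expect_equal(res$p_genotype[v], p_g, tolerance = 1e-10)
      expect_equal(res$p_age[v], p_a, tolerance = 1e-10)
    } else {
      expect_true(is.na(res$p_genotype[v]))
    }
  }
  expect_true(res$interaction_retained[2])
})

test_that("identical values yield no effects anywhere", {
  genotype <- rep(c("WT", "TG"), each = 4)
  age <- rep(c("4M", "6M"), 4)
  y <- matrix(1, 8, 5)
  res <- voxelwise_two_way_anova(y, genotype, age)
  expect_true(all(res$p_interaction == 1))
  expect_false(any(res$interaction_retained))
})

test_that("interaction type-I rate is near nominal on null voxels", {
  n_per <- 6
  genotype <- rep(c("WT", "TG"), each = 2 * n_per)
  age <- rep(rep(c("4M", "6M"), each = n_per), 2)
  hits <- 0L; total <- 0L
  for (r in 1:200) {
    y <- with_seed(400 + r, matrix(rnorm(4 * n_per * 40), 4 * n_per, 40))
    res <- voxelwise_two_way_anova(y, genotype, age)
    hits <- hits + sum(res$interaction_retained)
    total <- total + 40L
  }
  expect_lt(abs(hits / total - 0.05), 0.012)
})

test_that("BH step-up matches the hand computation exactly", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-15)
  expect_true(all(adj <= 0.05))        # all four kept at q = 0.05
  for (r in 1:20) {
    p <- with_seed(500 + r, runif(sample(3:10, 1))^2)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  }
})

test_that("in-plane cluster extent rule rejects 9 and keeps 10 voxels", {
  coords <- capdyn:::default_grid_coords(500)        # 10 x 10 x 5 grid
  blob9 <- which(coords[, 3] == 1 & coords[, 1] <= 3 &
                   coords[, 2] <= 3)[1:9]
  blob10 <- which(coords[, 3] == 2 & coords[, 1] <= 5 &
                    coords[, 2] <= 2)
  stopifnot(length(blob10) == 10)
  sel <- logical(500); sel[c(blob9, blob10)] <- TRUE
  comp <- in_plane_components(sel, coords)
  sizes <- tabulate(comp)
  expect_equal(sort(sizes), c(9, 10))
  keep <- comp %in% which(sizes >= 10)
  expect_false(any(keep[blob9]))
  expect_true(all(keep[blob10]))
})

test_that("post-hoc pipeline flags only the planted genotype difference", {
  coords <- capdyn:::default_grid_coords(200)        # 10 x 10 x 2 grid
  n_per <- 5
  genotype <- rep(c("WT", "TG"), each = 2 * n_per)
  age <- rep(rep(c("4M", "6M"), each = n_per), 2)
  y <- with_seed(35, matrix(rnorm(20 * 200, 0, 0.2), 20, 200))
  planted <- which(coords[, 3] == 1 & coords[, 1] <= 6 & coords[, 2] <= 2)
  stopifnot(length(planted) >= 10)
  # interaction-style effect: genotype difference at 4M only
  y[genotype == "TG" & age == "4M", planted] <-
    y[genotype == "TG" & age == "4M", planted] + 3
  eligible <- logical(200); eligible[c(planted, 150:155)] <- TRUE
  res <- posthoc_cluster_correct(y, genotype, age, eligible, coords,
                                 min_cluster = 10)
  expect_true(all(res[["4M"]]$sig_cluster[planted]))
  expect_false(any(res[["4M"]]$sig_cluster[-planted]))
  expect_false(any(res[["6M"]]$sig_cluster))
  # empty eligibility: empty masks, no error
  res0 <- posthoc_cluster_correct(y, genotype, age, logical(200), coords)
  expect_false(any(res0[["4M"]]$sig_cluster))
})

test_that("occurrence percentages count frames and sum to 100", {
  expect_equal(occurrence_percentage(c(1, 1, 2, 3), 3), c(50, 25, 25))
  expect_equal(occurrence_percentage(rep(2L, 10), 3), c(0, 100, 0))
  s <- with_seed(36, sample.int(6, 980, replace = TRUE))
  occ <- occurrence_percentage(s, 6)
  expect_equal(sum(occ), 100, tolerance = 1e-9)
  expect_true(all(abs(occ - 100 / 6) < 3 * 100 * sqrt(1 / 6 * 5 / 6 / 980) * 3))
  expect_error(occurrence_percentage(NA_integer_, 3), "empty")
})

test_that("mean duration enumerates runs, boundaries included", {
  expect_equal(mean_duration(c(2, 2, 1, 2), 2), c(1, 1.5))
  expect_equal(mean_duration(rep(3L, 10), 3), c(NA, NA, 10))
  # geometric run-length expectation on a persistence-q chain
  mk <- uniform_persistence_markov(6, 0.85)
  s <- generate_state_sequence(mk, 100000L, seed = 55)
  durs <- mean_duration(s, 6)
  pooled <- length(s) / length(rle(s)$lengths)
  expect_equal(pooled, 1 / (1 - 0.85), tolerance = 0.2 / 6.67)
  expect_true(all(abs(durs - 6.67) < 0.4))
})

test_that("repeated-measures ANOVA separates a planted WT-only age effect", {
  subj <- sprintf("S%02d", 1:12)
  genotype <- rep(c("WT", "TG"), each = 6)
  base <- with_seed(37, rnorm(12, 20, 0.1))
  df <- rbind(
    data.frame(subject_id = subj, genotype = genotype, age = "4M",
               cap = 1L, value = base),
    data.frame(subject_id = subj, genotype = genotype, age = "6M",
               cap = 1L, value = base + ifelse(genotype == "WT", 5, 0) +
                 with_seed(38, rnorm(12, 0, 0.1))))
  res <- rm_anova_metric(df)
  expect_lt(res$effects$p_interaction, 0.05)
  expect_true(res$effects$interaction_retained)
  ph <- res$posthoc
  expect_lt(ph$p[ph$contrast == "WT: 4M vs 6M"], 0.01)
  expect_gt(ph$p[ph$contrast == "TG: 4M vs 6M"], 0.05)
  # all-identical values: no effects
  df0 <- df; df0$value <- 1
  res0 <- rm_anova_metric(df0)
  expect_equal(res0$effects$p_interaction, 1)
})

test_that("repeated-measures interaction type-I rate is near nominal", {
  subj <- sprintf("S%02d", 1:12)
  genotype <- rep(c("WT", "TG"), each = 6)
  hits <- 0L
  for (r in 1:200) {
    vals <- with_seed(600 + r, rnorm(24))
    df <- data.frame(subject_id = rep(subj, 2), genotype = rep(genotype, 2),
                     age = rep(c("4M", "6M"), each = 12), value = vals)
    res <- rm_anova_metric(df)
    hits <- hits + res$effects$interaction_retained
  }
  expect_lt(abs(hits / 200 - 0.05), 0.04)
})

test_that("temporal metrics tables feed the ANOVA wrapper end to end", {
  st <- fixture_states(4, 100, seed = 40)
  co <- fixture_cohort(seed = 40, n_per_cell = 3, n_frames = 200,
                       noise_sd = 0.2, states = st)
  seqs <- co$truth$sequences
  metrics <- temporal_metrics(seqs, co$manifest, 4)
  expect_equal(nrow(metrics), nrow(co$manifest) * 4)
  sums <- tapply(metrics$occurrence_pct,
                 paste(metrics$subject_id, metrics$age), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  tab <- rm_anova_temporal(metrics)
  expect_true(all(c("metric", "cap", "p_posthoc_fdr") %in% names(tab)))
  expect_equal(nrow(tab), 2 * 4 * 4)   # 2 metrics x 4 CAPs x 4 contrasts
})
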