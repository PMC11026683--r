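## Spatial and temporal CAP statistics: voxel-level one-sample T maps with
## Bonferroni control, voxel-wise two-way ANOVA (genotype x age) with
## interaction-dropping, BH-FDR post-hocs with in-plane cluster-extent
## correction, and occurrence/duration metrics with repeated-measures ANOVA.

#' One-sample T map over a CAP's frames
#'
#' For every voxel, tests the mean of the unthresholded z-scored signals
#' across the frames assigned to one CAP (in one group or the whole cohort)
#' against zero; two-tailed p-values are Bonferroni-corrected across mask
#' voxels within the map.
#'
#' @param frames m x n matrix of z-scored frames assigned to the CAP.
#' @param alpha significance level after Bonferroni correction.
#' @return list with `t`, `df`, `p` (raw), `p_bonf`, `sig_pos`, `sig_neg`
#'   logical masks, and `n_zero_variance` (voxels with undefined T, marked
#'   non-significant).
#' @export
one_sample_t_map <- function(frames, alpha = 0.01) {
  n <- ncol(frames)
  if (n < 3L) stop("need at least 3 frames for a T map", call. = FALSE)
  m <- nrow(frames)
  mu <- rowMeans(frames)
  sdev <- row_sds(frames)
  tstat <- mu / (sdev / sqrt(n))
  bad <- which(sdev == 0)
  tstat[bad] <- NA_real_
  if (length(bad))
    message(sprintf("one_sample_t_map: %d zero-variance voxel(s) marked non-significant",
                    length(bad)))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  p_bonf <- pmin(p * m, 1)
  sig <- !is.na(p_bonf) & p_bonf < alpha
  list(t = tstat, df = n - 1L, p = p, p_bonf = p_bonf,
       sig_pos = sig & mu > 0, sig_neg = sig & mu < 0,
       n_zero_variance = length(bad))
}

#' Subject-level mean CAP maps
#'
#' The subject-level spatial observation entering the voxel-wise ANOVA:
#' for each scan, the mean unthresholded z-map over that scan's frames
#' assigned to the CAP.
#'
#' @param labels integer CAP label per concatenated frame.
#' @param concat the matching [concat_frames()].
#' @param K number of CAPs.
#' @return list per CAP with `y` (scans x m matrix; `NA` row when the scan
#'   has no frame in that CAP), and `design` (scan, subject, genotype, age).
#' @export
subject_cap_maps <- function(labels, concat, K) {
  scan_f <- factor(concat$prov$scan, levels = unique(concat$prov$scan))
  scans <- levels(scan_f)
  design <- unique(data.frame(scan = concat$prov$scan,
                              subject_id = concat$prov$subject_id,
                              genotype = concat$prov$genotype,
                              age = concat$prov$age,
                              stringsAsFactors = FALSE))
  design <- design[match(scans, design$scan), ]
  rownames(design) <- NULL
  out <- vector("list", K)
  for (k in seq_len(K)) {
    y <- matrix(NA_real_, length(scans), nrow(concat$x))
    for (i in seq_along(scans)) {
      idx <- which(labels == k & concat$prov$scan == scans[i])
      if (length(idx)) y[i, ] <- rowMeans(concat$x[, idx, drop = FALSE])
    }
    out[[k]] <- list(y = y, design = design)
  }
  out
}

## residual sums of squares of Y (n x m) under the projection onto X
rss_under <- function(y, x) {
  q <- qr.Q(qr(x))
  r <- y - q %*% (t(q) %*% y)
  colSums(r^2)
}

#' Voxel-wise two-way ANOVA with interaction dropping
#'
#' Fits `value ~ genotype * age` per voxel (Type II sums of squares,
#' vectorized across voxels). Where the interaction is not significant
#' (p > `alpha_int`) the additive model's main effects are reported;
#' elsewhere the voxel is marked interaction-significant and main effects
#' are not interpreted.
#'
#' @param y n x m matrix of subject-level values (scans x voxels); rows with
#'   `NA` are dropped with a message.
#' @param genotype,age factors of length n.
#' @param alpha_int interaction retention threshold (default 0.05).
#' @return list with per-voxel `p_interaction`, `p_genotype`, `p_age`
#'   (additive-model main effects, `NA` where the interaction is retained)
#'   and logical `interaction_retained`.
#' @export
voxelwise_two_way_anova <- function(y, genotype, age, alpha_int = 0.05) {
  genotype <- factor(genotype); age <- factor(age)
  keep <- rowSums(is.na(y)) == 0
  if (!all(keep)) {
    message(sprintf("voxelwise_two_way_anova: dropping %d scan(s) with missing maps",
                    sum(!keep)))
    y <- y[keep, , drop = FALSE]
    genotype <- droplevels(genotype[keep]); age <- droplevels(age[keep])
  }
  if (any(table(genotype, age) < 2L))
    stop("need >= 2 subjects per genotype-age cell", call. = FALSE)
  n <- nrow(y)
  x_full <- stats::model.matrix(~ genotype * age)
  x_add  <- stats::model.matrix(~ genotype + age)
  x_gen  <- stats::model.matrix(~ genotype)
  x_age  <- stats::model.matrix(~ age)

  rss_full <- rss_under(y, x_full)
  rss_add  <- rss_under(y, x_add)
  rss_gen  <- rss_under(y, x_gen)
  rss_age  <- rss_under(y, x_age)

  df_int <- ncol(x_full) - ncol(x_add)
  df_err_full <- n - ncol(x_full)
  f_int <- ((rss_add - rss_full) / df_int) / (rss_full / df_err_full)
  p_int <- pf(f_int, df_int, df_err_full, lower.tail = FALSE)
  ## zero residual variance with zero effect: define p = 1 (no evidence)
  p_int[rss_full == 0 & rss_add == 0] <- 1

  df_err_add <- n - ncol(x_add)
  f_gen <- ((rss_age - rss_add) / (ncol(x_add) - ncol(x_age))) /
    (rss_add / df_err_add)
  f_age <- ((rss_gen - rss_add) / (ncol(x_add) - ncol(x_gen))) /
    (rss_add / df_err_add)
  p_gen <- pf(f_gen, ncol(x_add) - ncol(x_age), df_err_add, lower.tail = FALSE)
  p_age <- pf(f_age, ncol(x_add) - ncol(x_gen), df_err_add, lower.tail = FALSE)
  p_gen[rss_add == 0 & rss_age == 0] <- 1
  p_age[rss_add == 0 & rss_gen == 0] <- 1

  retained <- !is.na(p_int) & p_int <= alpha_int
  p_gen[retained] <- NA_real_
  p_age[retained] <- NA_real_
  list(p_interaction = p_int, p_genotype = p_gen, p_age = p_age,
       interaction_retained = retained)
}

#' In-plane connected components of a voxel set
#'
#' Components are computed within each slice (fixed z) under 8-neighbour
#' connectivity on the (x, y) grid.
#'
#' @param voxels logical vector (length m) or integer indices of voxels.
#' @param coords m x 3 voxel grid coordinates.
#' @return integer vector of length m: component id per voxel, 0 outside
#'   the set.
#' @export
in_plane_components <- function(voxels, coords) {
  m <- nrow(coords)
  sel <- if (is.logical(voxels)) which(voxels) else as.integer(voxels)
  comp <- integer(m)
  if (!length(sel)) return(comp)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  lut <- new.env(hash = TRUE, parent = emptyenv())
  for (i in sel) assign(key[i], i, envir = lut)
  nb <- expand.grid(dx = -1:1, dy = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
  cid <- 0L
  for (start in sel) {
    if (comp[start]) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (j in seq_len(nrow(nb))) {
        kk <- paste(coords[v, 1] + nb$dx[j], coords[v, 2] + nb$dy[j],
                    coords[v, 3])
        w <- if (exists(kk, envir = lut, inherits = FALSE))
          get(kk, envir = lut) else 0L
        if (w && !comp[w]) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Post-hoc genotype contrasts with FDR and cluster-extent correction
#'
#' Among voxels with a retained genotype x age interaction that are
#' significant in at least one group's one-sample map, performs per-voxel
#' WT-vs-TG two-sample t-tests at each age; BH-FDR is applied across all
#' tested voxel-age hypotheses, and FDR-significant voxels are then kept
#' only when they form in-plane (within-slice, 8-connected) components of
#' at least `min_cluster` voxels.
#'
#' @param y n x m subject-level map matrix (as in
#'   [voxelwise_two_way_anova()]).
#' @param genotype,age factors of length n.
#' @param eligible logical length-m vector: interaction-retained voxels that
#'   are significant in >= 1 group's one-sample map.
#' @param coords m x 3 voxel grid coordinates.
#' @param min_cluster minimum in-plane component size (default 10).
#' @param q FDR level (default 0.05).
#' @return list per age: `t` (WT minus TG), `p`, `p_fdr` (vector over all
#'   tested hypotheses, stored per age), `sig_fdr`, `sig_cluster` logical
#'   masks. Empty eligibility yields empty masks, not an error.
#' @export
posthoc_cluster_correct <- function(y, genotype, age, eligible, coords,
                                    min_cluster = 10L, q = 0.05) {
  genotype <- factor(genotype, levels = c("WT", "TG"))
  ages <- sort(unique(as.character(age)))
  m <- ncol(y)
  test_idx <- which(eligible)
  res <- list()
  tab <- data.frame()
  for (a in ages) {
    tv <- rep(NA_real_, m); pv <- rep(NA_real_, m)
    if (length(test_idx)) {
      ya <- y[age == a, , drop = FALSE]
      ga <- genotype[age == a]
      n1 <- sum(ga == "WT"); n2 <- sum(ga == "TG")
      y1 <- ya[ga == "WT", test_idx, drop = FALSE]
      y2 <- ya[ga == "TG", test_idx, drop = FALSE]
      m1 <- colMeans(y1); m2 <- colMeans(y2)
      s2 <- (colSums((y1 - rep(m1, each = n1))^2) +
             colSums((y2 - rep(m2, each = n2))^2)) / (n1 + n2 - 2)
      tt <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
      tv[test_idx] <- tt
      pv[test_idx] <- 2 * pt(-abs(tt), df = n1 + n2 - 2)
    }
    res[[a]] <- list(t = tv, p = pv)
    if (length(test_idx))
      tab <- rbind(tab, data.frame(age = a, voxel = test_idx,
                                   p = pv[test_idx]))
  }
  if (nrow(tab)) tab$p_fdr <- bh_adjust(tab$p)
  for (a in ages) {
    p_fdr <- rep(NA_real_, m)
    if (nrow(tab)) {
      rows <- tab$age == a
      p_fdr[tab$voxel[rows]] <- tab$p_fdr[rows]
    }
    sig_fdr <- !is.na(p_fdr) & p_fdr < q
    comp <- in_plane_components(sig_fdr, coords)
    keep_comp <- which(tabulate(comp) >= min_cluster)
    sig_cluster <- comp %in% keep_comp & sig_fdr
    res[[a]]$p_fdr <- p_fdr
    res[[a]]$sig_fdr <- sig_fdr
    res[[a]]$sig_cluster <- sig_cluster
  }
  res
}

#' Occurrence percentage per CAP
#'
#' @param labels integer CAP labels of one subject-scan (`NA` allowed for
#'   unclassified frames; they are excluded from the denominator).
#' @param K number of CAPs.
#' @return numeric vector of length K summing to 100.
#' @export
occurrence_percentage <- function(labels, K) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("empty label sequence", call. = FALSE)
  100 * tabulate(labels, K) / length(labels)
}

#' Mean duration (consecutive frames) per CAP
#'
#' Mean length of maximal runs of each label; runs touching the scan
#' boundary count as ordinary runs. CAPs that never occur get `NA`.
#'
#' @inheritParams occurrence_percentage
#' @return numeric vector of length K (frames).
#' @export
mean_duration <- function(labels, K) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("empty label sequence", call. = FALSE)
  r <- rle(labels)
  out <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    runs <- r$lengths[r$values == k]
    if (length(runs)) out[k] <- mean(runs)
  }
  out
}

#' Temporal metrics table for a cohort
#'
#' @param sequences named list of per-scan label sequences (names
#'   `subject.age` as produced by [extract_caps()]).
#' @param manifest cohort manifest (`subject_id`, `genotype`, `age`).
#' @param K number of CAPs.
#' @return tidy data.frame: subject_id, genotype, age, cap, occurrence_pct,
#'   duration.
#' @export
temporal_metrics <- function(sequences, manifest, K) {
  keys <- paste(manifest$subject_id, manifest$age, sep = ".")
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    seq_i <- sequences[[keys[i]]]
    if (is.null(seq_i)) stop("no label sequence for scan ", keys[i], call. = FALSE)
    occ <- occurrence_percentage(seq_i, K)
    dur <- mean_duration(seq_i, K)
    out[[i]] <- data.frame(subject_id = manifest$subject_id[i],
                           genotype = manifest$genotype[i],
                           age = manifest$age[i], cap = seq_len(K),
                           occurrence_pct = occ, duration = dur,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Repeated-measures two-way ANOVA on one temporal metric
#'
#' Classical mixed two-way ANOVA with genotype as the between-subject
#' factor, age as the repeated (within-subject) factor and a random subject
#' intercept, fitted with `aov(value ~ genotype * age + Error(subject))`.
#' When the interaction is not significant (p > 0.05) the additive model's
#' main effects are reported. Post-hoc contrasts: WT-vs-TG at each age
#' (two-sample t) and 4M-vs-6M within each genotype (paired t).
#'
#' @param df data.frame with `subject_id`, `genotype`, `age`, `value`;
#'   subjects missing one age are excluded with a message.
#' @return list with `effects` (p-values for genotype, age, interaction;
#'   `interaction_retained`) and `posthoc` (contrast table with raw p;
#'   callers apply BH across the families they report together).
#' @export
rm_anova_metric <- function(df) {
  wide <- table(df$subject_id, df$age)
  complete <- rownames(wide)[rowSums(wide > 0) == ncol(wide)]
  if (length(complete) < nrow(wide))
    message(sprintf("rm_anova_metric: excluding %d subject(s) missing an age",
                    nrow(wide) - length(complete)))
  df <- df[df$subject_id %in% complete, ]
  df$subject_id <- factor(df$subject_id)
  df$genotype <- factor(df$genotype, levels = c("WT", "TG"))
  df$age <- factor(df$age)
  no_var <- sd(df$value) == 0

  p_from_aov <- function(fit) {
    s <- summary(fit)
    ps <- c(genotype = NA_real_, age = NA_real_, interaction = NA_real_)
    for (stratum in s) {
      t_ <- stratum[[1L]]
      rn <- trimws(rownames(t_))
      for (term in rn) {
        p <- t_[term == rn, "Pr(>F)"]
        if (term == "genotype") ps["genotype"] <- p
        if (term == "age") ps["age"] <- p
        if (term == "genotype:age") ps["interaction"] <- p
      }
    }
    ps
  }
  if (no_var) {
    eff <- c(genotype = 1, age = 1, interaction = 1)
  } else {
    full <- stats::aov(value ~ genotype * age + Error(subject_id), data = df)
    eff <- p_from_aov(full)
    if (is.na(eff["interaction"]) || eff["interaction"] > 0.05) {
      add <- stats::aov(value ~ genotype + age + Error(subject_id), data = df)
      eff[c("genotype", "age")] <- p_from_aov(add)[c("genotype", "age")]
      eff["interaction"] <- if (is.na(eff["interaction"])) 1 else eff["interaction"]
    }
  }
  retained <- eff[["interaction"]] <= 0.05

  ages <- levels(df$age)
  gts <- levels(df$genotype)
  ph <- data.frame()
  safe_p <- function(x, y, paired) {
    if (sd(c(x, y)) == 0 || (paired && sd(x - y) == 0))
      return(if (all(x == y)) 1 else 0)
    t.test(x, y, paired = paired, var.equal = !paired)$p.value
  }
  for (a in ages) {
    x <- df$value[df$age == a & df$genotype == gts[1]]
    y <- df$value[df$age == a & df$genotype == gts[2]]
    ph <- rbind(ph, data.frame(contrast = sprintf("%s: %s vs %s", a, gts[1], gts[2]),
                               p = safe_p(x, y, paired = FALSE)))
  }
  for (g in gts) {
    sub <- df[df$genotype == g, ]
    sub <- sub[order(sub$subject_id, sub$age), ]
    x <- sub$value[sub$age == ages[1]]
    y <- sub$value[sub$age == ages[2]]
    ph <- rbind(ph, data.frame(contrast = sprintf("%s: %s vs %s", g, ages[1], ages[2]),
                               p = safe_p(x, y, paired = TRUE)))
  }
  list(effects = list(p_genotype = eff[["genotype"]], p_age = eff[["age"]],
                      p_interaction = eff[["interaction"]],
                      interaction_retained = retained),
       posthoc = ph)
}

#' Repeated-measures ANOVA over all CAPs and both temporal metrics
#'
#' Runs [rm_anova_metric()] per CAP for occurrence percentage and duration
#' and applies BH-FDR to the post-hoc contrasts within each metric family
#' (all CAPs together, matching how the contrasts are reported side by
#' side).
#'
#' @param metrics a [temporal_metrics()] table.
#' @return data.frame with one row per CAP x metric x contrast plus effect
#'   p-values.
#' @export
rm_anova_temporal <- function(metrics) {
  out <- list()
  for (metric in c("occurrence_pct", "duration")) {
    rows <- list()
    for (k in sort(unique(metrics$cap))) {
      df <- metrics[metrics$cap == k, ]
      df$value <- df[[metric]]
      df <- df[!is.na(df$value), ]
      r <- rm_anova_metric(df)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, cap = k,
        p_genotype = r$effects$p_genotype, p_age = r$effects$p_age,
        p_interaction = r$effects$p_interaction,
        interaction_retained = r$effects$interaction_retained,
        contrast = r$posthoc$contrast, p_posthoc = r$posthoc$p,
        stringsAsFactors = FALSE)
    }
    fam <- do.call(rbind, rows)
    fam$p_posthoc_fdr <- bh_adjust(fam$p_posthoc)
    out[[metric]] <- fam
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
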