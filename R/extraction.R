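## CAP extraction: frame thresholding, K-means++ clustering of single time
## frames under correlation distance (1 - Pearson), explained-variance model
## selection via the 0.5% fractional-gain elbow rule, and construction of
## cohort- and group-level CAP maps organized as CAP/anti-CAP pairs.

#' Threshold one frame to its activation extremes
#'
#' Keeps the values of the top `top_pct` percent and bottom `bottom_pct`
#' percent of voxels and zeroes the rest. A rank-based cutoff is used:
#' `ceiling(top_pct/100 * m)` highest and `ceiling(bottom_pct/100 * m)`
#' lowest values survive, with ties broken by voxel index, so the retained
#' count is deterministic. A frame with no variance (e.g. all zeros) is
#' degenerate: everything is zeroed and the event is flagged via the
#' `"degenerate"` attribute.
#'
#' @param frame numeric vector of z-scores over mask voxels.
#' @param top_pct percentage of highest values kept (default 10).
#' @param bottom_pct percentage of lowest values kept (default 5).
#' @return thresholded vector, same length as `frame`.
#' @export
threshold_frame <- function(frame, top_pct = 10, bottom_pct = 5) {
  m <- length(frame)
  if (m < 20L) stop("frame too short to threshold (m < 20)", call. = FALSE)
  if (max(frame) == min(frame)) {
    out <- rep(0, m)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n_top <- ceiling(top_pct / 100 * m)
  n_bot <- ceiling(bottom_pct / 100 * m)
  ord <- order(frame, seq_len(m))   # ascending, ties by voxel index
  keep <- c(ord[seq_len(n_bot)], ord[(m - n_top + 1L):m])
  out <- rep(0, m)
  out[keep] <- frame[keep]
  out
}

#' Threshold every column of a voxels-by-frames matrix
#'
#' @param x m x N matrix (voxels x frames).
#' @inheritParams threshold_frame
#' @return matrix of the same shape; degenerate frame indices are recorded
#'   in the `"degenerate_frames"` attribute.
#' @export
threshold_frames <- function(x, top_pct = 10, bottom_pct = 5) {
  out <- apply(x, 2L, threshold_frame, top_pct = top_pct,
               bottom_pct = bottom_pct)
  degen <- which(apply(x, 2L, function(v) max(v) == min(v)))
  if (length(degen))
    message(sprintf("threshold_frames: %d degenerate frame(s) zeroed",
                    length(degen)))
  attr(out, "degenerate_frames") <- degen
  out
}

## correlation distance machinery operates on frames normalized to zero
## mean and unit L2 norm over voxels, for which 1 - cor(x, c) = 1 - x . c

kmeanspp_seed <- function(y, K) {
  n <- nrow(y)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  min_d2 <- (1 - drop(y %*% y[centers[1L], ]))^2
  if (K > 1L) for (k in 2L:K) {
    w <- min_d2
    if (sum(w) <= 0) w <- rep(1, n)
    centers[k] <- sample.int(n, 1L, prob = w)
    d2 <- (1 - drop(y %*% y[centers[k], ]))^2
    min_d2 <- pmin(min_d2, d2)
  }
  y[centers, , drop = FALSE]
}

normalize_rows <- function(c_mat) {
  c_mat <- c_mat - rowMeans(c_mat)
  c_mat / sqrt(rowSums(c_mat^2))
}

lloyd_correlation <- function(y, cent, max_iter = 100L) {
  n <- nrow(y); K <- nrow(cent)
  lab <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    sim <- y %*% t(cent)
    new_lab <- max.col(sim, ties.method = "first")
    ## empty clusters: reseed at the frame farthest from its own centroid
    repeat {
      empty <- setdiff(seq_len(K), unique(new_lab))
      if (!length(empty)) break
      d2 <- (1 - sim[cbind(seq_len(n), new_lab)])^2
      for (k in empty) {
        far <- which.max(d2)
        cent[k, ] <- y[far, ]
        d2[far] <- -Inf
      }
      sim <- y %*% t(cent)
      new_lab <- max.col(sim, ties.method = "first")
    }
    if (all(new_lab == lab)) break
    lab <- new_lab
    for (k in seq_len(K))
      cent[k, ] <- colMeans(y[lab == k, , drop = FALSE])
    cent <- normalize_rows(cent)
  }
  sim <- y %*% t(cent)
  lab <- max.col(sim, ties.method = "first")
  d <- 1 - sim[cbind(seq_len(n), lab)]
  list(labels = lab, centroids = cent, D = sum(d^2))
}

#' Cluster thresholded frames with K-means++ under correlation distance
#'
#' Partitions the N frames into K clusters by (locally) minimizing
#' `D = sum_k sum_{j in k} d^2(z_j, c_k)` with `d = 1 - Pearson correlation`,
#' the best of `n_restarts` K-means++-seeded Lloyd runs by objective value.
#' Zeros introduced by thresholding are treated as data (no masking).
#' Zero-variance frames cannot enter a correlation and are excluded with a
#' message; their labels are `NA`.
#'
#' @param x m x N matrix of (thresholded) frames.
#' @param K number of clusters (`K < N`).
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts independent seeded restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @param init optional K x m matrix of initial centroids; when supplied,
#'   a single Lloyd run starts from these centroids (used for oracle
#'   comparisons).
#' @return object of class `frame_partition`: `K`, `labels` (length N,
#'   `NA` for excluded frames), `centroids` (K x m, zero-mean unit-norm
#'   rows), `N` (frames clustered), `m`, `D`, `sizes`, `seed`,
#'   `n_restarts`, `excluded`.
#' @export
cluster_frames <- function(x, K, seed = 1L, n_restarts = 10L,
                           max_iter = 100L, init = NULL) {
  n_all <- ncol(x)
  yn <- normalize_frames(x)
  excluded <- attr(yn, "degenerate")
  keep <- setdiff(seq_len(n_all), excluded)
  if (length(excluded))
    message(sprintf("cluster_frames: excluding %d zero-variance frame(s)",
                    length(excluded)))
  n <- length(keep)
  if (K >= n) stop("K must be smaller than the number of frames", call. = FALSE)
  y <- t(yn[, keep, drop = FALSE])

  best <- NULL
  if (!is.null(init)) {
    best <- lloyd_correlation(y, normalize_rows(as.matrix(init)), max_iter)
  } else {
    for (r in seq_len(n_restarts)) {
      fit <- with_seed(seed + r - 1L, {
        cent <- kmeanspp_seed(y, K)
        lloyd_correlation(y, cent, max_iter)
      })
      if (is.null(best) || fit$D < best$D) best <- fit
    }
  }
  labels <- rep(NA_integer_, n_all)
  labels[keep] <- best$labels
  structure(list(K = as.integer(K), labels = labels,
                 centroids = best$centroids, N = n, m = ncol(y), D = best$D,
                 sizes = tabulate(best$labels, K),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 excluded = excluded),
            class = "frame_partition")
}

#' Explained variance of a frame partition
#'
#' Within-cluster variance `V_w = D / N`; between-cluster variance
#' `V_B = (1/N) * sum_k n_k d^2(c_k, c)` with the global centroid
#' `c = sum_k (n_k / N) c_k` (cluster centroids weighted by cluster size);
#' explained variance `EV = V_B / (V_w + V_B)`.
#'
#' @param partition a [cluster_frames()] result.
#' @return list with `V_w`, `V_B`, `EV`, `global_centroid`.
#' @export
explained_variance <- function(partition) {
  if (partition$N == 0L) stop("empty partition", call. = FALSE)
  v_w <- partition$D / partition$N
  w <- partition$sizes / partition$N
  c_glob <- drop(w %*% partition$centroids)
  ## a degenerate (constant) global centroid has no defined correlation;
  ## treat it as uncorrelated with every cluster centroid (distance 1)
  cors <- if (sd(c_glob) == 0) rep(0, partition$K)
          else drop(cor(t(partition$centroids), c_glob))
  d2 <- (1 - cors)^2
  v_b <- sum(partition$sizes * d2) / partition$N
  ev <- if (v_w + v_b == 0) 0 else v_b / (v_w + v_b)
  list(V_w = v_w, V_B = v_b, EV = ev, global_centroid = c_glob)
}

#' Explained-variance curve over a range of cluster counts
#'
#' @param x m x N matrix of thresholded frames.
#' @param k_range contiguous integer range of cluster counts (default 2:30).
#' @inheritParams cluster_frames
#' @return data.frame with one row per K: `K, D, V_w, V_B, EV, gain`
#'   (fractional EV gain over K - 1, `NA` for the first K).
#' @export
variance_curve <- function(x, k_range = 2:30, seed = 1L, n_restarts = 10L) {
  rows <- lapply(k_range, function(K) {
    part <- cluster_frames(x, K, seed = seed, n_restarts = n_restarts)
    ev <- explained_variance(part)
    data.frame(K = K, D = part$D, V_w = ev$V_w, V_B = ev$V_B, EV = ev$EV)
  })
  curve <- do.call(rbind, rows)
  curve$gain <- c(NA, diff(curve$EV) / head(curve$EV, -1))
  curve
}

#' Select the elbow of an explained-variance curve
#'
#' Operationalizes EV saturation with the fractional-gain rule: gain at K is
#' `(EV_K - EV_{K-1}) / EV_{K-1}`. Under the default `"all_subsequent"`
#' rule the elbow is the smallest K whose gains for every larger K in the
#' curve stay below `gain_threshold` (0.5% by default); `"next_only"`
#' instead returns the first K whose own gain is below the threshold.
#'
#' @param curve a [variance_curve()] data.frame (contiguous K range).
#' @param gain_threshold fractional-gain threshold (default 0.005).
#' @param rule `"all_subsequent"` (default) or `"next_only"`.
#' @return the selected K; if no K satisfies the rule (other than the last
#'   K vacuously), the maximum K is returned with a warning.
#' @export
select_k_elbow <- function(curve, gain_threshold = 0.005,
                           rule = c("all_subsequent", "next_only")) {
  rule <- match.arg(rule)
  stopifnot(all(diff(curve$K) == 1L))
  ks <- curve$K
  gains <- curve$gain
  if (rule == "next_only") {
    hit <- which(!is.na(gains) & gains < gain_threshold)
    if (!length(hit)) {
      warning("no elbow: no fractional gain below threshold", call. = FALSE)
      return(max(ks))
    }
    return(ks[hit[1L]])
  }
  ok <- vapply(seq_along(ks), function(i) {
    later <- gains[seq_along(ks) > i]
    all(later < gain_threshold)
  }, logical(1))
  first <- which(ok)[1L]
  if (first == length(ks) && !is.na(gains[length(ks)]) &&
      gains[length(ks)] >= gain_threshold)
    warning("no elbow: explained variance still gaining at the largest K",
            call. = FALSE)
  ks[first]
}

#' Concatenate subject scans into one combined image-series
#'
#' @param scans list of [voxel_time_series()] sharing a mask.
#' @return list with `x` (m x N matrix of frames) and `prov` (data.frame
#'   with `scan`, `subject_id`, `genotype`, `age`, `frame` per column of
#'   `x`), plus the shared `coords`.
#' @export
concat_frames <- function(scans) {
  stopifnot(length(scans) >= 1L)
  m <- nrow(scans[[1L]]$data)
  for (s in scans) if (nrow(s$data) != m)
    stop("scans disagree on mask size", call. = FALSE)
  x <- do.call(cbind, lapply(scans, `[[`, "data"))
  prov <- do.call(rbind, lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    data.frame(scan = names(scans)[i] %||% as.character(i),
               subject_id = s$subject_id, genotype = s$genotype, age = s$age,
               frame = seq_len(ncol(s$data)), stringsAsFactors = FALSE)
  }))
  list(x = x, prov = prov, coords = scans[[1L]]$coords)
}

#' Cohort- and group-level CAP maps
#'
#' For each CAP, the unthresholded z-scored frames assigned to it are
#' averaged voxel-wise: across all frames (cohort level) and within each
#' genotype-age cell. The cohort map of a CAP is by construction the
#' frame-count-weighted mean of its cell maps.
#'
#' @param partition a [cluster_frames()] result on the thresholded frames.
#' @param concat the matching [concat_frames()] of unthresholded frames.
#' @return object of class `cap_map_set`: `cohort` (K x m), `cells` (named
#'   list of K x m matrices with `NA` rows for empty combinations),
#'   `cell_counts` (K x cells frame counts), `occurrence_pct` (cohort-level
#'   percentage per CAP), `order` (identity until
#'   [pair_and_order_caps()] is applied), `missing` (empty cell-CAP
#'   combinations).
#' @export
compute_cap_maps <- function(partition, concat) {
  lab <- partition$labels
  if (length(lab) != ncol(concat$x))
    stop("partition and series are not frame-aligned", call. = FALSE)
  K <- partition$K
  m <- nrow(concat$x)
  cohort <- matrix(NA_real_, K, m)
  for (k in seq_len(K)) {
    idx <- which(lab == k)
    if (length(idx)) cohort[k, ] <- rowMeans(concat$x[, idx, drop = FALSE])
  }
  cell_lab <- paste(concat$prov$genotype, concat$prov$age, sep = ".")
  cells <- sort(unique(cell_lab))
  cell_maps <- list()
  cell_counts <- matrix(0L, K, length(cells), dimnames = list(NULL, cells))
  missing <- character(0)
  for (cl in cells) {
    mat <- matrix(NA_real_, K, m)
    for (k in seq_len(K)) {
      idx <- which(lab == k & cell_lab == cl)
      cell_counts[k, cl] <- length(idx)
      if (length(idx)) mat[k, ] <- rowMeans(concat$x[, idx, drop = FALSE])
      else missing <- c(missing, sprintf("CAP%d:%s", k, cl))
    }
    cell_maps[[cl]] <- mat
  }
  occ <- 100 * tabulate(lab[!is.na(lab)], K) / sum(!is.na(lab))
  structure(list(cohort = cohort, cells = cell_maps,
                 cell_counts = cell_counts, occurrence_pct = occ,
                 order = seq_len(K), pairs = NULL, pair_cor = NULL,
                 missing = missing),
            class = "cap_map_set")
}

#' Order CAPs into anti-correlated pairs
#'
#' Greedily pairs CAPs on the most negative pairwise Pearson correlation of
#' their cohort maps; pairs are sorted from strongest to weakest
#' anti-correlation and, within a pair, the CAP with the higher occurrence
#' percentage comes first. With an odd number of CAPs the leftover CAP is
#' appended unpaired and flagged; a "pair" whose correlation is not negative
#' is flagged as well.
#'
#' @param maps a [compute_cap_maps()] result.
#' @return the `cap_map_set` with `order` (new display order as original CAP
#'   indices), `pairs` (list of index pairs in display order), `pair_cor`,
#'   and `flags`; maps, occurrence and counts are reordered accordingly.
#' @export
pair_and_order_caps <- function(maps) {
  K <- nrow(maps$cohort)
  cc <- cor(t(maps$cohort))
  left <- seq_len(K)
  pairs <- list(); pcor <- c(); flags <- character(0)
  while (length(left) >= 2L) {
    sub <- cc[left, left, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    p <- c(left[ij[1L]], left[ij[2L]])
    if (cc[p[1L], p[2L]] >= 0)
      flags <- c(flags, sprintf("pair (%d,%d) not anti-correlated (r=%.3f)",
                                p[1L], p[2L], cc[p[1L], p[2L]]))
    ## within-pair order: higher occurrence first
    if (maps$occurrence_pct[p[2L]] > maps$occurrence_pct[p[1L]]) p <- rev(p)
    pairs[[length(pairs) + 1L]] <- p
    pcor <- c(pcor, cc[p[1L], p[2L]])
    left <- setdiff(left, p)
  }
  ord_pairs <- order(pcor)          # strongest (most negative) first
  pairs <- pairs[ord_pairs]
  pcor <- pcor[ord_pairs]
  new_order <- unlist(pairs)
  if (length(left)) {
    flags <- c(flags, sprintf("CAP %d left unpaired (odd K)", left))
    new_order <- c(new_order, left)
  }
  maps$order <- new_order
  maps$pairs <- pairs
  maps$pair_cor <- pcor
  maps$flags <- flags
  maps$cohort <- maps$cohort[new_order, , drop = FALSE]
  maps$cells <- lapply(maps$cells, function(m) m[new_order, , drop = FALSE])
  maps$cell_counts <- maps$cell_counts[new_order, , drop = FALSE]
  maps$occurrence_pct <- maps$occurrence_pct[new_order]
  maps
}

#' Full CAP extraction on a set of conditioned scans
#'
#' Concatenates all scans into one combined image-series, thresholds each
#' frame (top 10% / bottom 5% by rank), scans the explained-variance curve
#' over `k_range` (unless `K` is fixed), selects the elbow, clusters at the
#' selected K and builds cohort/group CAP maps ordered as anti-pairs.
#'
#' @param scans named list of conditioned [voxel_time_series()].
#' @param k_range K values for the variance curve (ignored when `K` given).
#' @param K optional fixed cluster count; skips model selection.
#' @param top_pct,bottom_pct thresholding percentages.
#' @param seed integer seed.
#' @param n_restarts K-means restarts per K.
#' @param gain_threshold elbow fractional-gain threshold.
#' @return list with `curve`, `K`, `partition`, `maps`, `concat` provenance
#'   (`prov`), and per-scan label sequences (`sequences`).
#' @export
extract_caps <- function(scans, k_range = 2:30, K = NULL, top_pct = 10,
                         bottom_pct = 5, seed = 1L, n_restarts = 10L,
                         gain_threshold = 0.005) {
  concat <- concat_frames(scans)
  xt <- threshold_frames(concat$x, top_pct, bottom_pct)
  curve <- NULL
  if (is.null(K)) {
    curve <- variance_curve(xt, k_range, seed = seed, n_restarts = n_restarts)
    K <- select_k_elbow(curve, gain_threshold)
  }
  partition <- cluster_frames(xt, K, seed = seed, n_restarts = n_restarts)
  maps <- compute_cap_maps(partition, concat)
  maps <- pair_and_order_caps(maps)
  ## relabel frame labels into display (pair-sorted) order
  relabel <- match(seq_len(K), maps$order)
  labels <- relabel[partition$labels]
  sequences <- split(labels, factor(concat$prov$scan, levels = unique(concat$prov$scan)))
  list(curve = curve, K = K, partition = partition, maps = maps,
       prov = concat$prov, labels = labels, sequences = sequences,
       coords = concat$coords)
}
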