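## Leakage-controlled classification of subjects into genotype(-age) groups
## from CAP features. Reference CAPs, the significant-voxel union defining
## spatial features, and feature standardization statistics are all derived
## from training subjects only; test subjects enter only at prediction time.

#' Stratified subject-level train/test split
#'
#' Splits subjects (not scans) so a subject's two ages never straddle the
#' split. Per stratum, `round(train_frac * n)` subjects train, with at
#' least one test subject guaranteed.
#'
#' @param subjects data.frame with `subject_id` and a `class` column to
#'   stratify on (one row per subject).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed; same seed gives an identical split.
#' @return list with `train` and `test` subject-id vectors.
#' @export
split_stratified <- function(subjects, train_frac = 0.8, seed = 1L) {
  stopifnot(is.data.frame(subjects), all(c("subject_id", "class") %in%
                                           names(subjects)))
  counts <- table(subjects$class)
  if (any(counts < 2L))
    stop("every class needs >= 2 subjects to split", call. = FALSE)
  with_seed(seed, {
    train <- character(0)
    for (cl in names(counts)) {
      ids <- subjects$subject_id[subjects$class == cl]
      n <- length(ids)
      n_train <- min(round(train_frac * n), n - 1L)
      n_train <- max(n_train, 1L)
      train <- c(train, sample(ids, n_train))
    }
    list(train = sort(train),
         test = sort(setdiff(subjects$subject_id, train)))
  })
}

#' Derive reference CAPs from training scans only
#'
#' Re-runs the extraction pipeline (threshold, cluster, map, anti-pair
#' ordering) on the concatenated training frames at a fixed K (normally the
#' cohort-level elbow K), and computes the significant-voxel union defining
#' spatial features: per CAP, the voxels significant (one-sample T,
#' Bonferroni, p < `alpha`) in at least one training group's map.
#'
#' @param train_scans named list of conditioned training
#'   [voxel_time_series()].
#' @param K number of CAPs; if `NULL`, the elbow is selected on
#'   `k_range` and falls back to `fallback_K` with a warning on failure.
#' @param top_pct,bottom_pct thresholding percentages.
#' @param seed integer seed.
#' @param n_restarts K-means restarts.
#' @param alpha one-sample-map significance level (Bonferroni-corrected).
#' @param k_range,fallback_K model-selection controls when `K` is `NULL`.
#' @return list with `extraction` (an [extract_caps()] result on the
#'   training frames), `centroids` (K x m in display order), `sig_union`
#'   (list per CAP of voxel indices), `K`.
#' @export
derive_training_caps <- function(train_scans, K = NULL, top_pct = 10,
                                 bottom_pct = 5, seed = 1L, n_restarts = 10L,
                                 alpha = 0.01, k_range = 2:30,
                                 fallback_K = 6L) {
  if (is.null(K)) {
    K <- tryCatch({
      concat <- concat_frames(train_scans)
      xt <- threshold_frames(concat$x, top_pct, bottom_pct)
      curve <- variance_curve(xt, k_range, seed = seed,
                              n_restarts = n_restarts)
      select_k_elbow(curve)
    }, warning = function(w) {
      warning("elbow selection failed on training data; falling back to K = ",
              fallback_K, call. = FALSE)
      fallback_K
    })
  }
  ex <- extract_caps(train_scans, K = K, top_pct = top_pct,
                     bottom_pct = bottom_pct, seed = seed,
                     n_restarts = n_restarts)
  centroids <- ex$partition$centroids[ex$maps$order, , drop = FALSE]

  ## significant-voxel union per CAP across training genotype-age groups
  cell_lab <- paste(ex$prov$genotype, ex$prov$age, sep = ".")
  concat_x <- do.call(cbind, lapply(train_scans, `[[`, "data"))
  sig_union <- vector("list", K)
  for (k in seq_len(K)) {
    u <- logical(ex$partition$m)
    for (cl in unique(cell_lab)) {
      idx <- which(ex$labels == k & cell_lab == cl)
      if (length(idx) < 3L) next
      tm <- one_sample_t_map(concat_x[, idx, drop = FALSE], alpha = alpha)
      u <- u | tm$sig_pos | tm$sig_neg
    }
    sig_union[[k]] <- which(u)
  }
  list(extraction = ex, centroids = centroids, sig_union = sig_union, K = K)
}

#' Assign a scan's frames to reference CAP centroids
#'
#' Each frame is thresholded and assigned to the reference centroid with
#' the smallest correlation distance; exact ties resolve to the lowest CAP
#' index. Frames that are degenerate after thresholding (no variance) are
#' unclassified (`NA`) and excluded from downstream metrics.
#'
#' @param scan a conditioned [voxel_time_series()].
#' @param centroids K x m reference centroid matrix.
#' @param top_pct,bottom_pct thresholding percentages.
#' @return integer vector of CAP labels (length T, `NA` = unclassified).
#' @export
assign_frames_to_reference <- function(scan, centroids, top_pct = 10,
                                       bottom_pct = 5) {
  if (ncol(centroids) != nrow(scan$data))
    stop("centroid dimension does not match mask size", call. = FALSE)
  xt <- suppressMessages(threshold_frames(scan$data, top_pct, bottom_pct))
  xn <- normalize_frames(xt)
  degenerate <- attr(xn, "degenerate")
  cn <- normalize_rows(as.matrix(centroids))
  sim <- t(xn) %*% t(cn)
  lab <- max.col(sim, ties.method = "first")
  lab[degenerate] <- NA_integer_
  lab
}

scan_class <- function(manifest, classes, keys) {
  if (classes == "4class")
    paste(manifest$genotype, manifest$age, sep = ".")[match(keys, paste(
      manifest$subject_id, manifest$age, sep = "."))]
  else
    manifest$genotype[match(keys, paste(manifest$subject_id, manifest$age,
                                        sep = "."))]
}

build_features <- function(scans, reference, mode) {
  K <- reference$K
  feats <- lapply(names(scans), function(key) {
    scan <- scans[[key]]
    lab <- assign_frames_to_reference(scan, reference$centroids)
    if (mode == "temporal") {
      occ <- occurrence_percentage(lab, K)
      dur <- mean_duration(lab, K)
      dur[is.na(dur)] <- 0
      c(occ, dur)
    } else {
      unlist(lapply(seq_len(K), function(k) {
        vox <- reference$sig_union[[k]]
        if (!length(vox)) return(numeric(0))
        idx <- which(lab == k)
        if (!length(idx)) return(rep(0, length(vox)))
        rowMeans(scan$data[vox, idx, drop = FALSE])
      }))
    }
  })
  do.call(rbind, feats)
}

#' Train and evaluate the regularized multinomial classifier
#'
#' Per iteration: a fresh stratified subject-level split, reference CAPs
#' and feature definitions re-derived from the training scans only,
#' ridge-penalized multinomial logistic regression
#' (`glmnet(alpha = 0, lambda = lambda)`) on training-standardized
#' features, and test accuracy on the held-out subjects. A chance baseline
#' re-fits the same split with the training class labels shuffled. The
#' accuracy distributions are compared with a paired Wilcoxon signed-rank
#' test and test predictions are pooled into a row-normalized confusion
#' matrix.
#'
#' @param scans named list (keys `subject.age`) of conditioned
#'   [voxel_time_series()].
#' @param manifest cohort manifest (`subject_id`, `genotype`, `age`).
#' @param mode `"spatial"` or `"temporal"` features.
#' @param classes `"4class"` (genotype x age) or `"2class"` (genotype at
#'   one `age`).
#' @param age age used for 2-class runs (`"4M"` or `"6M"`).
#' @param n_iter split iterations (default 50).
#' @param seed integer seed; iteration i splits with `seed + i`.
#' @param K number of reference CAPs (pass the cohort-level elbow K).
#' @param lambda ridge penalty (fixed, default 1).
#' @param train_frac training fraction (default 0.8).
#' @param n_restarts K-means restarts inside each training extraction.
#' @return object of class `classification_result`: per-iteration
#'   `accuracy` and `chance`, `confusion` (row-normalized over pooled test
#'   predictions), `p_value` (Wilcoxon), `n_iter`, `classes`, `mode`.
#' @export
train_eval <- function(scans, manifest, mode = c("spatial", "temporal"),
                       classes = c("4class", "2class"), age = "4M",
                       n_iter = 50L, seed = 1L, K = 6L, lambda = 1,
                       train_frac = 0.8, n_restarts = 3L) {
  mode <- match.arg(mode)
  classes <- match.arg(classes)
  if (classes == "2class") {
    manifest <- manifest[manifest$age == age, , drop = FALSE]
    scans <- scans[paste(manifest$subject_id, manifest$age, sep = ".")]
  }
  subjects <- unique(manifest[, c("subject_id", "genotype")])
  subjects$class <- subjects$genotype

  acc <- numeric(n_iter); chance <- numeric(n_iter)
  class_levels <- sort(unique(scan_class(manifest, classes,
                                         paste(manifest$subject_id,
                                               manifest$age, sep = "."))))
  confusion <- matrix(0, length(class_levels), length(class_levels),
                      dimnames = list(class_levels, class_levels))
  for (it in seq_len(n_iter)) {
    split <- split_stratified(subjects, train_frac, seed = seed + it)
    keys <- paste(manifest$subject_id, manifest$age, sep = ".")
    train_keys <- keys[manifest$subject_id %in% split$train]
    test_keys <- keys[manifest$subject_id %in% split$test]
    reference <- suppressMessages(derive_training_caps(
      scans[train_keys], K = K, seed = seed + it, n_restarts = n_restarts))
    x_train <- build_features(scans[train_keys], reference, mode)
    x_test <- build_features(scans[test_keys], reference, mode)
    y_train <- scan_class(manifest, classes, train_keys)
    y_test <- scan_class(manifest, classes, test_keys)

    mu <- colMeans(x_train)
    sdev <- apply(x_train, 2L, sd)
    sdev[sdev == 0 | is.na(sdev)] <- 1
    x_train <- scale(x_train, mu, sdev)
    x_test <- scale(x_test, mu, sdev)

    acc[it] <- fit_predict_accuracy(x_train, y_train, x_test, y_test,
                                    lambda, class_levels, confusion_env = NULL,
                                    pool = function(true, pred) {
      confusion[cbind(true, pred)] <<- confusion[cbind(true, pred)] + 1
    })
    y_shuf <- with_seed(seed * 1000L + it, sample(y_train))
    chance[it] <- fit_predict_accuracy(x_train, y_shuf, x_test, y_test,
                                       lambda, class_levels)
  }
  p_value <- tryCatch(
    suppressWarnings(wilcox.test(acc, chance, paired = TRUE)$p.value),
    error = function(e) NA_real_)
  confusion <- confusion / pmax(rowSums(confusion), 1)
  structure(list(accuracy = acc, chance = chance, confusion = confusion,
                 p_value = p_value, n_iter = n_iter, classes = classes,
                 mode = mode),
            class = "classification_result")
}

fit_predict_accuracy <- function(x_train, y_train, x_test, y_test, lambda,
                                 class_levels, confusion_env = NULL,
                                 pool = NULL) {
  y_train <- factor(y_train, levels = class_levels)
  if (ncol(x_train) < 2L) {       # glmnet needs >= 2 predictors
    x_train <- cbind(x_train, 0)
    x_test <- cbind(x_test, 0)
  }
  if (nlevels(droplevels(y_train)) < 2L) {
    ## degenerate shuffle: constant prediction
    pred <- rep(as.character(y_train[1L]), length(y_test))
  } else {
    fit <- glmnet::glmnet(x_train, y_train, family = "multinomial",
                          alpha = 0, lambda = lambda)
    pred <- as.character(predict(fit, newx = x_test, type = "class",
                                 s = lambda))
  }
  if (!is.null(pool)) pool(as.character(y_test), pred)
  mean(pred == as.character(y_test))
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s, %s features, %d iterations\n",
              x$classes, x$mode, x$n_iter))
  cat(sprintf("  median accuracy %.3f vs chance %.3f (Wilcoxon p = %.3g)\n",
              stats::median(x$accuracy), stats::median(x$chance), x$p_value))
  invisible(x)
}
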