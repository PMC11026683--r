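## Signal conditioning chain: trim -> band-pass -> trim -> quadratic detrend
## -> nuisance regression -> voxel-wise z-scoring. The fixed order and frame
## budgets (6 + 4 frames cut per end, so a 1,000-frame scan conditions to
## 980 frames) follow standard rodent rsfMRI practice.

#' Conditioning configuration
#'
#' @param trim_pre frames cut at each end before filtering.
#' @param band band-pass edges in Hz, `c(low, high)`.
#' @param order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @param trim_post frames cut at each end after filtering.
#' @param detrend_order polynomial detrending order (2 = quadratic).
#' @param nuisance optional T x r matrix of nuisance regressors, aligned to
#'   the frames that remain after both trims.
#' @return object of class `conditioning_config`.
#' @export
conditioning_config <- function(trim_pre = 6L, band = c(0.01, 0.2),
                                order = 2L, trim_post = 4L,
                                detrend_order = 2L, nuisance = NULL) {
  if (trim_pre < 0L || trim_post < 0L) stop("trims must be >= 0", call. = FALSE)
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2])
    stop("`band` must be c(low, high) with 0 <= low < high", call. = FALSE)
  structure(list(trim_pre = as.integer(trim_pre), band = band,
                 order = as.integer(order), trim_post = as.integer(trim_post),
                 detrend_order = as.integer(detrend_order),
                 nuisance = nuisance),
            class = "conditioning_config")
}

#' Remove frames at both ends of a scan
#'
#' @param series a [voxel_time_series()].
#' @param n_each_end frames removed at the start and at the end.
#' @return trimmed `voxel_ts` with `T - 2 * n_each_end` frames.
#' @export
trim_frames <- function(series, n_each_end) {
  tt <- ncol(series$data)
  if (n_each_end < 0L) stop("`n_each_end` must be >= 0", call. = FALSE)
  if (tt <= 2L * n_each_end)
    stop("trimming would leave no frames (T <= 2n)", call. = FALSE)
  if (n_each_end == 0L) return(series)
  keep <- (n_each_end + 1L):(tt - n_each_end)
  series$data <- series$data[, keep, drop = FALSE]
  series
}

#' Design a digital Butterworth band-pass filter
#'
#' Classic design path: analog low-pass prototype poles, low-pass to
#' band-pass transformation at the pre-warped edges, then the bilinear
#' transform. Coefficients agree with reference DSP implementations to
#' machine precision.
#'
#' @param order prototype order (the band-pass filter has `2 * order` poles).
#' @param low,high band edges in Hz.
#' @param fs sampling frequency in Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order, low, high, fs) {
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  poles <- unlist(lapply(proto, function(p) {
    disc <- sqrt((p * bw / 2)^2 - w0^2)
    c(p * bw / 2 + disc, p * bw / 2 - disc)
  }))
  zeros <- rep(0 + 0i, order)
  gain <- bw^order
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  kd <- Re(gain * prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(b = Re(kd * poly_from_roots(zd)), a = Re(poly_from_roots(pd)))
}

poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

## steady-state initial state of the direct-form II transposed filter for a
## unit-step input, so that filtering a constant produces no start-up
## transient (the classic filtfilt initial-condition construction)
iir_step_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  comp <- rbind(-a[-1], cbind(diag(n - 2L), rep(0, n - 2L)))
  solve(diag(n - 1L) - t(comp), b[-1] - a[-1] * b[1])
}

## direct-form II transposed IIR filter applied along rows of x (m x T);
## zi (per unit input) scales with each row's first sample
iir_filter_rows <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  n <- max(nb, na)
  b <- c(b, rep(0, n - nb)) / a[1]
  a <- c(a, rep(0, n - na)) / a[1]
  m <- nrow(x); tt <- ncol(x)
  y <- matrix(0, m, tt)
  z <- if (is.null(zi)) matrix(0, m, n - 1L) else outer(x[, 1L], zi)
  for (t in seq_len(tt)) {
    xt <- x[, t]
    yt <- b[1] * xt + z[, 1L]
    if (n > 2L)
      for (j in seq_len(n - 2L))
        z[, j] <- b[j + 1L] * xt + z[, j + 1L] - a[j + 1L] * yt
    z[, n - 1L] <- b[n] * xt - a[n] * yt
    y[, t] <- yt
  }
  y
}

## zero-phase filtering with odd-reflection end padding (scipy-style filtfilt
## without initial-condition optimization; the pad length of 3 * (ntaps - 1)
## suppresses edge transients, and trim_post removes what remains)
filtfilt_rows <- function(b, a, x) {
  npad <- 3L * max(length(a), length(b))
  tt <- ncol(x)
  if (tt <= npad)
    stop("time series too short for zero-phase filtering", call. = FALSE)
  left <- 2 * x[, 1L] - x[, npad + 2L - seq_len(npad), drop = FALSE]
  right <- 2 * x[, tt] - x[, tt - seq_len(npad), drop = FALSE]
  ext <- cbind(left, x, right)
  zi <- iir_step_zi(b, a)
  y <- iir_filter_rows(b, a, ext, zi)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y <- iir_filter_rows(b, a, y, zi)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y[, npad + seq_len(tt), drop = FALSE]
}

#' Band-pass filter every voxel trace
#'
#' Applies the Butterworth design of [butter_bandpass()] forward-backward
#' (zero phase). The frame count is unchanged; callers are expected to trim
#' filter edges afterwards.
#'
#' @param series a [voxel_time_series()].
#' @param band band edges in Hz.
#' @param order Butterworth prototype order.
#' @return filtered `voxel_ts`.
#' @export
bandpass <- function(series, band = c(0.01, 0.2), order = 2L) {
  fs <- 1 / series$tr
  if (band[2] >= fs / 2)
    stop("upper band edge at or above Nyquist frequency", call. = FALSE)
  f <- butter_bandpass(order, band[1], band[2], fs)
  series$data <- filtfilt_rows(f$b, f$a, series$data)
  series
}

#' Remove a least-squares quadratic trend per voxel
#'
#' @param series a [voxel_time_series()].
#' @param degree polynomial degree (2 = quadratic).
#' @return detrended `voxel_ts`; residuals are orthogonal to
#'   `{1, t, ..., t^degree}`.
#' @export
detrend_quadratic <- function(series, degree = 2L) {
  tt <- ncol(series$data)
  if (tt < degree + 1L)
    stop("need more than `degree` + 1 frames to detrend", call. = FALSE)
  t_idx <- seq_len(tt)
  basis <- qr.Q(qr(outer(t_idx - mean(t_idx), 0:degree, `^`)))
  series$data <- series$data - (series$data %*% basis) %*% t(basis)
  series
}

#' Regress nuisance signals out of every voxel trace
#'
#' Projects each voxel trace onto the orthogonal complement of
#' `span{1, regressors}` (the intercept is implicit). Rank-deficient
#' regressor sets trigger a warning and are handled through an orthonormal
#' basis of the span (pseudoinverse behaviour).
#'
#' @param series a [voxel_time_series()].
#' @param regressors T x r matrix of nuisance time courses.
#' @return `voxel_ts` of residuals.
#' @export
regress_nuisance <- function(series, regressors) {
  regressors <- as.matrix(regressors)
  tt <- ncol(series$data)
  if (nrow(regressors) != tt)
    stop("regressor length must equal the number of frames", call. = FALSE)
  x <- cbind(1, regressors)
  qrx <- qr(x)
  if (qrx$rank < ncol(x))
    warning("rank-deficient nuisance regressors; using pseudoinverse projection",
            call. = FALSE)
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  series$data <- series$data - (series$data %*% q) %*% t(q)
  series
}

#' Normalize every voxel trace to zero mean and unit variance
#'
#' Uses the sample (n - 1) variance. Voxels with exactly zero variance
#' cannot be normalized; they are removed from the series (and from
#' `coords`) rather than zeroed silently, with the excluded row indices
#' recorded in the `excluded_voxels` attribute and a message emitted.
#'
#' @param series a [voxel_time_series()].
#' @return z-scored `voxel_ts`.
#' @export
zscore_voxels <- function(series) {
  mu <- rowMeans(series$data)
  sdev <- row_sds(series$data)
  bad <- which(sdev == 0 | is.na(sdev))
  if (length(bad)) {
    message(sprintf("zscore_voxels: excluding %d zero-variance voxel(s) from the mask",
                    length(bad)))
    series$data <- series$data[-bad, , drop = FALSE]
    series$coords <- series$coords[-bad, , drop = FALSE]
    mu <- mu[-bad]; sdev <- sdev[-bad]
  }
  series$data <- (series$data - mu) / sdev
  attr(series, "excluded_voxels") <- bad
  series
}

#' Run the full conditioning chain on one scan
#'
#' Fixed order: trim(`trim_pre`) -> band-pass -> trim(`trim_post`) ->
#' polynomial detrend -> nuisance regression -> z-score. On a 1,000-frame
#' scan with the default configuration the output has 980 frames.
#'
#' @param series a [voxel_time_series()].
#' @param cfg a [conditioning_config()].
#' @param verbose log frame counts per stage.
#' @return conditioned `voxel_ts` (z-units).
#' @export
condition_series <- function(series, cfg = conditioning_config(),
                             verbose = FALSE) {
  say <- function(stage, s) if (verbose)
    message(sprintf("condition[%s] %s: %d frames", series$subject_id, stage,
                    ncol(s$data)))
  s <- trim_frames(series, cfg$trim_pre); say("trim_pre", s)
  s <- bandpass(s, cfg$band, cfg$order); say("bandpass", s)
  s <- trim_frames(s, cfg$trim_post); say("trim_post", s)
  s <- detrend_quadratic(s, cfg$detrend_order)
  if (!is.null(cfg$nuisance)) s <- regress_nuisance(s, cfg$nuisance)
  s <- zscore_voxels(s)
  say("done", s)
  s
}
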