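# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept at desk scale (hundreds of voxels, <= 1000 frames).

fixture_states <- function(n_states = 6L, n_voxels = 500L, seed = 1L) {
  state_spec(n_states = n_states, n_voxels = n_voxels, seed = seed)
}

# the default desk-scale world: 6 anti-paired states on 500 voxels,
# persistence 0.85, 980-frame scans, 2 subjects per genotype-age cell
fixture_cohort <- function(seed = 1L, n_per_cell = 2L, n_frames = 980L,
                           noise_sd = 0.3, states = fixture_states(),
                           ...) {
  design <- cohort_design(n_per_cell = n_per_cell, n_frames = n_frames,
                          noise_sd = noise_sd, states = states,
                          seed = seed, ...)
  generate_cohort(design)
}

# small scan for conditioning tests
fixture_scan <- function(m = 50L, tt = 500L, seed = 7L, tr = 0.6) {
  dat <- with_seed(seed, matrix(rnorm(m * tt), m, tt))
  voxel_time_series(dat, capdyn:::default_grid_coords(m), tr = tr,
                    subject_id = "S1", genotype = "WT", age = "4M")
}

# match recovered CAP maps to planted patterns greedily by |correlation|;
# returns the matched correlation per planted state
match_maps_to_patterns <- function(maps, patterns) {
  cc <- abs(cor(t(maps), patterns))
  n <- ncol(patterns)
  out <- numeric(n)
  used <- integer(0)
  for (k in seq_len(n)) {
    cand <- cc[, k]
    cand[used] <- -Inf
    i <- which.max(cand)
    out[k] <- cc[i, k]
    used <- c(used, i)
  }
  out
}

# --- independent oracles (kept deliberately naive) -----------------------

# explained variance by direct transcription of the definitions
oracle_explained_variance <- function(frames, labels, centroids) {
  n <- ncol(frames)
  K <- nrow(centroids)
  d2 <- function(x, y) (1 - cor(x, y))^2
  D <- 0
  for (j in seq_len(n))
    D <- D + d2(frames[, j], centroids[labels[j], ])
  v_w <- D / n
  n_k <- tabulate(labels, K)
  c_glob <- rep(0, ncol(centroids))
  for (k in seq_len(K)) c_glob <- c_glob + n_k[k] / n * centroids[k, ]
  v_b <- 0
  for (k in seq_len(K)) v_b <- v_b + n_k[k] * d2(centroids[k, ], c_glob)
  v_b <- v_b / n
  list(V_w = v_w, V_B = v_b, EV = v_b / (v_w + v_b))
}

# naive Lloyd iteration under correlation distance from given start
# centroids; shares the package's centroid convention (mean of frames
# normalized to zero mean / unit L2 norm, re-centered and re-normalized)
# but computes every distance with stats::cor in explicit loops
oracle_lloyd <- function(frames, init, max_iter = 100L) {
  n <- ncol(frames)
  K <- nrow(init)
  norm1 <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) }
  yn <- apply(frames, 2L, norm1)
  cent <- init
  lab <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    new_lab <- integer(n)
    for (j in seq_len(n)) {
      d <- vapply(seq_len(K), function(k) 1 - cor(frames[, j], cent[k, ]),
                  numeric(1))
      new_lab[j] <- which.min(d)
    }
    if (all(new_lab == lab)) break
    lab <- new_lab
    for (k in seq_len(K))
      cent[k, ] <- norm1(rowMeans(yn[, lab == k, drop = FALSE]))
  }
  D <- 0
  for (j in seq_len(n)) D <- D + (1 - cor(frames[, j], cent[lab[j], ]))^2
  list(labels = lab, D = D)
}

# transition counts by explicit pair enumeration
oracle_count_transitions <- function(seqs, K) {
  out <- matrix(0, K, K)
  for (s in seqs)
    if (length(s) >= 2L)
      for (t in 2:length(s))
        out[s[t - 1L], s[t]] <- out[s[t - 1L], s[t]] + 1
  out
}

# BH step-up by hand: adjusted p = min_{j >= rank} m * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

# squared magnitude response of the forward-backward filter at frequency f
filtfilt_gain <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(h)^2
}

# enumerate all K^L label sequences of length L
all_sequences <- function(K, L) {
  grid <- do.call(expand.grid, rep(list(seq_len(K)), L))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
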