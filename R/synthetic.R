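## Synthetic cohort generator.
##
## Every downstream stage of the pipeline is exercised on data with known
## ground truth: a small set of spatial co-activation topographies (organized
## as sign-flipped anti-pairs) driven by a per-subject Markov state sequence
## with high self-transition probability, plus voxel-wise Gaussian noise and
## optional multiplicative group effects.

#' Specification of planted co-activation states
#'
#' Builds `n_states` spatial topographies over the mask voxels. States come
#' in anti-pairs: state 2k is the sign-flipped copy of state 2k-1, so their
#' patterns correlate at exactly -1. Each base pattern has a compact "hub"
#' of strongly loaded voxels on a weak Gaussian background, mimicking the
#' localized co-activation hubs of empirical CAP maps; patterns are centered
#' over voxels and scaled to unit standard deviation.
#'
#' @param n_states number of states (>= 2); odd counts leave the last state
#'   unpaired.
#' @param n_voxels number of mask voxels each pattern spans.
#' @param hub_frac fraction of voxels forming each base pattern's hub.
#' @param hub_gain raw loading of hub voxels before scaling.
#' @param bg_sd standard deviation of the background loading.
#' @param amplitudes per-state scalar gain, recycled to `n_states`.
#' @param seed integer seed; the spec is a pure function of its arguments.
#' @return object of class `state_spec` with elements `n_states`, `patterns`
#'   (`n_voxels` x `n_states` matrix), `amplitudes`, `anti_pairs`.
#' @export
state_spec <- function(n_states = 6L, n_voxels = 500L, hub_frac = 0.1,
                       hub_gain = 3, bg_sd = 0.3, amplitudes = 1,
                       seed = 1L) {
  if (n_states < 2L) stop("`n_states` must be >= 2", call. = FALSE)
  n_base <- ceiling(n_states / 2)
  patterns <- with_seed(seed, {
    hub_n <- max(1L, round(hub_frac * n_voxels))
    p <- matrix(0, n_voxels, n_states)
    ## disjoint hubs keep base patterns close to mutually orthogonal
    starts <- floor(seq(1L, n_voxels - hub_n + 1L, length.out = n_base))
    for (b in seq_len(n_base)) {
      v <- rnorm(n_voxels, 0, bg_sd)
      v[starts[b] + seq_len(hub_n) - 1L] <- hub_gain + rnorm(hub_n, 0, bg_sd / 2)
      v <- v - mean(v)
      v <- v / sd(v)
      i <- 2L * b - 1L
      p[, i] <- v
      if (i + 1L <= n_states) p[, i + 1L] <- -v
    }
    p
  })
  anti_pairs <- lapply(seq_len(floor(n_states / 2)),
                       function(b) c(2L * b - 1L, 2L * b))
  structure(list(n_states = as.integer(n_states),
                 patterns = patterns,
                 amplitudes = rep_len(amplitudes, n_states),
                 anti_pairs = anti_pairs,
                 seed = as.integer(seed)),
            class = "state_spec")
}

#' Markov chain specification over planted states
#'
#' @param trans row-stochastic transition matrix including self-transitions.
#' @param require_irreducible enforce irreducibility (default). Absorbing
#'   chains (e.g. the identity matrix) are useful as degenerate fixtures and
#'   may be allowed explicitly; their "stationary" distribution is the
#'   leading left eigenvector and need not be unique.
#' @return object of class `markov_spec` with `trans` and the implied
#'   `stationary` distribution (leading left eigenvector).
#' @export
markov_spec <- function(trans, require_irreducible = TRUE) {
  trans <- as.matrix(trans)
  if (nrow(trans) != ncol(trans)) stop("`trans` must be square", call. = FALSE)
  if (any(trans < 0)) stop("`trans` must be non-negative", call. = FALSE)
  if (any(abs(rowSums(trans) - 1) > 1e-12))
    stop("rows of `trans` must sum to 1", call. = FALSE)
  ## irreducibility: reachability of the whole state graph
  k <- nrow(trans)
  reach <- (trans > 0) | diag(k) > 0
  for (i in seq_len(ceiling(log2(k)) + 1L)) reach <- (reach %*% reach) > 0
  if (require_irreducible && !all(reach))
    stop("`trans` is not irreducible", call. = FALSE)
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  statio <- Re(e$vectors[, i])
  statio <- statio / sum(statio)
  structure(list(trans = trans, stationary = statio, n_states = k),
            class = "markov_spec")
}

#' Uniform-persistence Markov specification
#'
#' Chain with constant self-transition probability and the remaining mass
#' spread uniformly over the other states; its stationary distribution is
#' uniform. The default persistence of 0.85 matches the regime in which
#' roughly 85% of frame-to-frame transitions are persistent.
#'
#' @param n_states number of states.
#' @param persistence self-transition probability in `[0, 1)`.
#' @return a [markov_spec()].
#' @export
uniform_persistence_markov <- function(n_states = 6L, persistence = 0.85) {
  off <- (1 - persistence) / (n_states - 1L)
  m <- matrix(off, n_states, n_states)
  diag(m) <- persistence
  markov_spec(m)
}

#' Sample a state sequence from a Markov specification
#'
#' The initial state is drawn from the stationary distribution (not fixed),
#' which removes transient bias from occupancy statistics.
#'
#' @param markov a [markov_spec()].
#' @param n_frames sequence length (>= 1).
#' @param seed integer seed; same seed gives an identical sequence.
#' @return integer vector of states in `1..n_states`.
#' @export
generate_state_sequence <- function(markov, n_frames, seed) {
  if (!inherits(markov, "markov_spec"))
    stop("`markov` must be a markov_spec", call. = FALSE)
  if (n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  k <- markov$n_states
  with_seed(seed, {
    s <- integer(n_frames)
    s[1L] <- sample.int(k, 1L, prob = markov$stationary)
    if (n_frames > 1L)
      for (t in 2L:n_frames)
        s[t] <- sample.int(k, 1L, prob = markov$trans[s[t - 1L], ])
    s
  })
}

#' One subject scan as a voxel-by-frame matrix
#'
#' Container for a single scan: `data` is an m x T matrix (m mask voxels,
#' T frames), `coords` maps each voxel row to its (x, y, z) grid position.
#'
#' @param data m x T numeric matrix.
#' @param coords m x 3 integer matrix of voxel grid coordinates.
#' @param tr repetition time in seconds.
#' @param subject_id,genotype,age scan metadata.
#' @return object of class `voxel_ts`.
#' @export
voxel_time_series <- function(data, coords, tr = 0.6,
                              subject_id = NA_character_,
                              genotype = NA_character_, age = NA_character_) {
  data <- as.matrix(data)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(data))
    stop("`coords` must have one row per voxel", call. = FALSE)
  structure(list(data = data, coords = coords, tr = tr,
                 subject_id = subject_id, genotype = genotype, age = age),
            class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("<voxel_ts> %s (%s, %s): %d voxels x %d frames, TR %.3gs\n",
              x$subject_id, x$genotype, x$age, nrow(x$data), ncol(x$data),
              x$tr))
  invisible(x)
}

#' Generate one subject scan from a planted state sequence
#'
#' Frame t equals `amplitude[state_t] * pattern[, state_t]` plus i.i.d.
#' Gaussian noise per voxel. Optional group effects multiply the signal part
#' (not the noise) on a voxel subset for matching cells. With
#' `raw_mode = TRUE` the z-scale signal is wrapped in a raw-like trace
#' (baseline offset, slow polynomial drift, out-of-band sinusoid) so the
#' signal-conditioning chain has something to remove.
#'
#' @param states a [state_spec()].
#' @param sequence integer state sequence.
#' @param cell group label `"<genotype>.<age>"` used to match `group_effects`.
#' @param noise_sd Gaussian noise standard deviation in z-units.
#' @param seed integer seed.
#' @param coords optional voxel coordinate matrix (defaults to a filled
#'   grid enumeration).
#' @param group_effects list of effects, each a list with elements `cells`
#'   (character vector of cell labels), `voxels` (indices), `scale`
#'   (multiplier) and optionally `states` (restrict to these states).
#' @param raw_mode logical; add baseline, drift and a 0.35 Hz sinusoid.
#' @param tr repetition time in seconds.
#' @param subject_id,genotype,age metadata passed to [voxel_time_series()].
#' @return a [voxel_time_series()].
#' @export
generate_subject_scan <- function(states, sequence, cell = "WT.4M",
                                  noise_sd = 0.3, seed = 1L, coords = NULL,
                                  group_effects = NULL, raw_mode = FALSE,
                                  tr = 0.6, subject_id = NA_character_,
                                  genotype = NA_character_,
                                  age = NA_character_) {
  if (!inherits(states, "state_spec"))
    stop("`states` must be a state_spec", call. = FALSE)
  if (length(sequence) < 1L) stop("empty state sequence", call. = FALSE)
  if (any(sequence < 1L | sequence > states$n_states))
    stop("sequence values outside 1..n_states", call. = FALSE)
  m <- nrow(states$patterns)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(coords)) coords <- default_grid_coords(m)
  if (nrow(coords) != m)
    stop("pattern length does not match mask size", call. = FALSE)

  signal <- states$patterns[, sequence, drop = FALSE] *
    rep(states$amplitudes[sequence], each = m)
  for (eff in group_effects %||% list()) {
    if (!cell %in% eff$cells) next
    frames_hit <- if (is.null(eff$states)) seq_along(sequence)
                  else which(sequence %in% eff$states)
    if (length(frames_hit))
      signal[eff$voxels, frames_hit] <- signal[eff$voxels, frames_hit] * eff$scale
  }
  noise <- with_seed(seed, matrix(rnorm(m * length(sequence), 0, noise_sd),
                                  m, length(sequence)))
  x <- signal + noise
  if (raw_mode) {
    t_idx <- seq_along(sequence)
    tt <- (t_idx - mean(t_idx)) / length(t_idx)
    drift <- outer(rep(1, m), 4 * tt + 6 * tt^2)
    sine <- outer(rep(1, m), 2 * sin(2 * pi * 0.35 * t_idx * tr))
    x <- 100 + 10 * x + drift + sine
  }
  voxel_time_series(x, coords, tr = tr, subject_id = subject_id,
                    genotype = genotype, age = age)
}

## enumerate a 10 x 10 x ceiling(m/100) grid (x fastest), first m voxels
default_grid_coords <- function(m, nx = 10L, ny = 10L) {
  nz <- ceiling(m / (nx * ny))
  g <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz)))
  g[seq_len(m), , drop = FALSE]
}

#' Cohort design for the synthetic generator
#'
#' Defaults mirror the desk-scale world used throughout the test-suite:
#' 6 states in anti-pairs on 500 mask voxels (10 x 10 x 5 grid), persistence
#' 0.85, 980 frames per scan (a 1,000-frame acquisition minus the 6 + 4
#' frames trimmed per end during conditioning), Gaussian noise sd 0.3, and
#' one subject per genotype (WT, TG) x age (4M, 6M) cell unless widened.
#'
#' @param n_per_cell subjects per genotype-age cell (>= 1). Subjects are
#'   longitudinal: the same subject id appears at both ages.
#' @param n_frames frames per scan (>= 50).
#' @param noise_sd Gaussian noise sd (z-units).
#' @param states a [state_spec()].
#' @param markov a [markov_spec()] shared by all cells.
#' @param group_effects list of multiplicative effects (see
#'   [generate_subject_scan()]).
#' @param markov_overrides optional named list (by cell label) of
#'   [markov_spec()] objects replacing `markov` for that cell.
#' @param raw_mode generate raw-like traces instead of z-scale signals.
#' @param seed integer master seed.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_cell = 2L, n_frames = 980L, noise_sd = 0.3,
                          states = state_spec(),
                          markov = uniform_persistence_markov(states$n_states),
                          group_effects = NULL, markov_overrides = NULL,
                          raw_mode = FALSE, seed = 1L) {
  if (n_per_cell < 1L) stop("`n_per_cell` must be >= 1", call. = FALSE)
  if (n_frames < 50L) stop("`n_frames` must be >= 50", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (markov$n_states != states$n_states)
    stop("`markov` and `states` disagree on the number of states", call. = FALSE)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 states = states, markov = markov,
                 group_effects = group_effects,
                 markov_overrides = markov_overrides,
                 raw_mode = raw_mode, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a synthetic cohort
#'
#' Produces one scan per subject per age with known ground truth. All
#' randomness derives deterministically from `design$seed`. When `dir` is
#' given, scans and the mask are written as NIfTI-1 volumes, the manifest as
#' CSV (`subject_id, genotype, age, path`), and the ground truth as JSON.
#'
#' @param design a [cohort_design()].
#' @param dir optional output directory; created if missing.
#' @return list with `manifest` (data.frame), `scans` (named list of
#'   [voxel_time_series()]), `truth` (state spec, per-cell Markov specs,
#'   per-scan state sequences and seeds), and `mask` info.
#' @export
generate_cohort <- function(design, dir = NULL) {
  if (!inherits(design, "cohort_design"))
    stop("`design` must be a cohort_design", call. = FALSE)
  genotypes <- c("WT", "TG")
  ages <- c("4M", "6M")
  m <- nrow(design$states$patterns)
  coords <- default_grid_coords(m)

  manifest <- data.frame()
  scans <- list()
  sequences <- list()
  seeds <- list()
  for (g in genotypes) {
    for (s in seq_len(design$n_per_cell)) {
      sid <- sprintf("%s%02d", g, s)
      for (a in ages) {
        cell <- paste(g, a, sep = ".")
        mk <- design$markov_overrides[[cell]] %||% design$markov
        ## independent, reproducible seed per scan
        scan_seed <- design$seed * 10000L +
          match(g, genotypes) * 1000L + s * 10L + match(a, ages)
        seq_s <- generate_state_sequence(mk, design$n_frames, seed = scan_seed)
        scan <- generate_subject_scan(
          design$states, seq_s, cell = cell, noise_sd = design$noise_sd,
          seed = scan_seed + 1L, coords = coords,
          group_effects = design$group_effects, raw_mode = design$raw_mode,
          subject_id = sid, genotype = g, age = a)
        key <- paste(sid, a, sep = ".")
        scans[[key]] <- scan
        sequences[[key]] <- seq_s
        seeds[[key]] <- scan_seed
        manifest <- rbind(manifest, data.frame(
          subject_id = sid, genotype = g, age = a, path = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(manifest) <- NULL
  truth <- list(states = design$states,
                markov = design$markov,
                markov_overrides = design$markov_overrides,
                sequences = sequences, seeds = seeds,
                design_seed = design$seed)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    grid_dim <- c(max(coords[, 1]), max(coords[, 2]), max(coords[, 3]))
    mask <- array(0L, grid_dim)
    mask[coords] <- 1L
    write_nifti(mask, file.path(dir, "mask.nii.gz"), datatype = 2L)
    for (key in names(scans)) {
      scan <- scans[[key]]
      vol <- array(0, c(grid_dim, ncol(scan$data)))
      idx4 <- cbind(coords[rep(seq_len(m), ncol(scan$data)), ],
                    rep(seq_len(ncol(scan$data)), each = m))
      vol[idx4] <- as.vector(scan$data)
      p <- file.path(dir, paste0(key, ".nii.gz"))
      write_nifti(vol, p, pixdim = c(1, 1, 1, scan$tr))
      manifest$path[paste(manifest$subject_id, manifest$age, sep = ".") == key] <- p
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(design_seed = design$seed,
           n_states = design$states$n_states,
           anti_pairs = design$states$anti_pairs,
           sequences = sequences, seeds = seeds),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, scans = scans, truth = truth,
       mask = list(coords = coords))
}
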