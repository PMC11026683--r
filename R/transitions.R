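## Inter-CAP transition analysis: group-pooled persistence and transition
## probabilities, per-subject label-permutation surrogate ensembles, and
## permutation tests for pathway significance, directionality preference
## (p_ij vs p_ji) and inter-group differences.
##
## Permutation p-values use the add-one convention
## p = (1 + #{surrogate >= observed}) / (1 + n_surrogates), which avoids
## exact zeros that would break the BH step-up.

validate_sequences <- function(sequences, K) {
  if (!length(sequences)) stop("no label sequences", call. = FALSE)
  sequences <- lapply(sequences, function(s) as.integer(s[!is.na(s)]))
  sequences <- sequences[vapply(sequences, length, 1L) > 0L]
  if (!length(sequences)) stop("all label sequences empty", call. = FALSE)
  rng <- range(unlist(sequences))
  if (rng[1] < 1L || rng[2] > K)
    stop("labels outside 1..K", call. = FALSE)
  sequences
}

#' Pooled transition counts over a group's subjects
#'
#' Counts (i, j) label pairs over consecutive frames within each scan and
#' sums over subjects; no pair spans a subject boundary. `NA` labels
#' (unclassified frames) are removed before counting.
#'
#' @param sequences list of per-subject integer label sequences.
#' @param K number of CAPs.
#' @return K x K numeric matrix of counts.
#' @export
count_transitions <- function(sequences, K) {
  sequences <- validate_sequences(sequences, K)
  count_transitions_cpp(sequences, as.integer(K))
}

#' Persistence probability per CAP
#'
#' `persistence_i = counts(i, i) / sum_j counts(i, j)`: the fraction of all
#' of CAP i's outgoing transitions (self and non-self) that are
#' self-transitions. CAPs with no outgoing transitions get `NA`.
#'
#' @param counts K x K transition count matrix.
#' @return numeric vector of length K.
#' @export
persistence_probabilities <- function(counts) {
  rs <- rowSums(counts)
  out <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  unname(out)
}

#' Non-self transition probability matrix
#'
#' `p_ij = counts(i, j) / sum_{j' != i} counts(i, j')` for `j != i`; the
#' diagonal is `NA`, as are rows with no non-self outgoing transition.
#'
#' @param counts K x K transition count matrix.
#' @return K x K matrix with `NA` diagonal; each defined row sums to 1.
#' @export
transition_probabilities <- function(counts) {
  K <- nrow(counts)
  nonself <- rowSums(counts) - diag(counts)
  out <- counts / nonself
  diag(out) <- NA_real_
  out[nonself == 0, ] <- NA_real_
  out
}

#' Surrogate ensemble by per-subject label permutation
#'
#' For each surrogate, every subject's full label sequence is permuted
#' uniformly at random (preserving that subject's label multiset and
#' sequence length) and the group-pooled persistence and non-self
#' transition probabilities are recomputed through the same code path as
#' the observed data.
#'
#' @param sequences list of per-subject integer label sequences.
#' @param K number of CAPs.
#' @param n_surrogates surrogates to draw (default 10000; fewer than 100
#'   triggers a resolution warning).
#' @param seed integer seed.
#' @return object of class `surrogate_ensemble` with `trans`
#'   (`n_surrogates` x K x K array), `persist` (`n_surrogates` x K matrix),
#'   `n_surrogates`, `seed`.
#' @export
surrogate_null <- function(sequences, K, n_surrogates = 10000L, seed = 1L) {
  sequences <- validate_sequences(sequences, K)
  if (n_surrogates < 100L)
    warning("fewer than 100 surrogates: poor p-value resolution", call. = FALSE)
  ens <- with_seed(seed,
    surrogate_ensemble_cpp(sequences, as.integer(K), as.integer(n_surrogates)))
  structure(list(trans = ens$trans, persist = ens$persist,
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed)),
            class = "surrogate_ensemble")
}

perm_p_ge <- function(observed, surrogate_draws) {
  (1 + sum(surrogate_draws >= observed, na.rm = TRUE)) /
    (1 + sum(!is.na(surrogate_draws)))
}

#' Permutation significance of transition probabilities
#'
#' For every ordered non-self pair, the one-sided permutation p-value is the
#' (add-one corrected) fraction of surrogates whose pooled `p_ij` meets or
#' exceeds the observed value; BH-FDR is applied across all ordered pairs.
#'
#' @param observed K x K observed transition probability matrix
#'   ([transition_probabilities()]).
#' @param ensemble a [surrogate_null()] computed on the same group.
#' @param q FDR level for the significance flags (default 0.05).
#' @return list with `p_raw`, `p_fdr` (K x K matrices, `NA` diagonal and
#'   missing pairs) and logical `significant`.
#' @export
pair_significance <- function(observed, ensemble, q = 0.05) {
  K <- nrow(observed)
  p_raw <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j || is.na(observed[i, j])) next
    p_raw[i, j] <- perm_p_ge(observed[i, j], ensemble$trans[, i, j])
  }
  tested <- which(!is.na(p_raw))
  p_fdr <- matrix(NA_real_, K, K)
  p_fdr[tested] <- bh_adjust(p_raw[tested])
  list(p_raw = p_raw, p_fdr = p_fdr,
       significant = !is.na(p_fdr) & p_fdr < q)
}

#' Directionality preference test (p_ij vs p_ji)
#'
#' For every unordered pair with a significant transition probability in at
#' least one direction, tests the observed difference `d = p_ij - p_ji`
#' against the surrogate distribution of the same difference, one-sided in
#' the direction of the observed preference; BH-FDR over the tested pairs.
#'
#' @param observed K x K observed transition probability matrix.
#' @param ensemble the group's [surrogate_null()].
#' @param significance a [pair_significance()] result for the same group.
#' @param q FDR level (default 0.05).
#' @return data.frame with one row per tested unordered pair: `from`, `to`
#'   (oriented so the observed difference is non-negative: preference
#'   from -> to), `d` (observed `p_from,to - p_to,from`), `p`, `p_fdr`,
#'   `significant`. Zero eligible pairs yield an empty data.frame.
#' @export
directionality_test <- function(observed, ensemble, significance, q = 0.05) {
  K <- nrow(observed)
  rows <- list()
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    if (!(significance$significant[i, j] || significance$significant[j, i]))
      next
    if (is.na(observed[i, j]) || is.na(observed[j, i])) next
    d_obs <- observed[i, j] - observed[j, i]
    d_sur <- ensemble$trans[, i, j] - ensemble$trans[, j, i]
    if (d_obs >= 0) {
      p <- perm_p_ge(d_obs, d_sur)
      rows[[length(rows) + 1L]] <- data.frame(from = i, to = j, d = d_obs, p = p)
    } else {
      p <- perm_p_ge(-d_obs, -d_sur)
      rows[[length(rows) + 1L]] <- data.frame(from = j, to = i, d = -d_obs, p = p)
    }
  }
  if (!length(rows))
    return(data.frame(from = integer(0), to = integer(0), d = numeric(0),
                      p = numeric(0), p_fdr = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p)
  out$significant <- out$p_fdr < q
  out
}

#' Inter-group difference test on transition and persistence probabilities
#'
#' Compares two groups' pooled probabilities: the observed difference
#' `delta = p^A - p^B` is tested two-sided against the distribution of
#' paired surrogate differences (the s-th surrogate of each group's
#' ensemble). Transition pairs are eligible when significant in at least
#' one group; persistence is tested for every CAP. BH-FDR is applied within
#' each family (pairs; persistence).
#'
#' @param obs_a,obs_b K x K observed transition probability matrices.
#' @param ens_a,ens_b the groups' [surrogate_null()] ensembles (equal
#'   `n_surrogates`).
#' @param sig_a,sig_b [pair_significance()] results for the two groups.
#' @param persist_a,persist_b observed persistence vectors
#'   ([persistence_probabilities()]).
#' @param q FDR level (default 0.05).
#' @return list with `pairs` (data.frame: from, to, delta, p, p_fdr,
#'   significant) and `persistence` (data.frame: cap, delta, p, p_fdr,
#'   significant).
#' @export
intergroup_difference_test <- function(obs_a, obs_b, ens_a, ens_b,
                                       sig_a, sig_b,
                                       persist_a, persist_b, q = 0.05) {
  if (ens_a$n_surrogates != ens_b$n_surrogates)
    stop("ensembles must have the same number of surrogates", call. = FALSE)
  K <- nrow(obs_a)
  if (!all(dim(obs_b) == c(K, K)))
    stop("groups analyzed with different K", call. = FALSE)
  rows <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    if (!(sig_a$significant[i, j] || sig_b$significant[i, j])) next
    if (is.na(obs_a[i, j]) || is.na(obs_b[i, j])) next
    delta <- obs_a[i, j] - obs_b[i, j]
    d_sur <- ens_a$trans[, i, j] - ens_b$trans[, i, j]
    p <- perm_p_ge(abs(delta), abs(d_sur))
    rows[[length(rows) + 1L]] <- data.frame(from = i, to = j, delta = delta, p = p)
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(from = integer(0), to = integer(0),
                           delta = numeric(0), p = numeric(0))
  if (nrow(pairs)) {
    pairs$p_fdr <- bh_adjust(pairs$p)
    pairs$significant <- pairs$p_fdr < q
  } else {
    pairs$p_fdr <- numeric(0); pairs$significant <- logical(0)
  }

  pers <- data.frame(cap = seq_len(K),
                     delta = persist_a - persist_b,
                     p = NA_real_)
  for (k in seq_len(K)) {
    if (is.na(pers$delta[k])) next
    d_sur <- ens_a$persist[, k] - ens_b$persist[, k]
    pers$p[k] <- perm_p_ge(abs(pers$delta[k]), abs(d_sur))
  }
  pers$p_fdr <- bh_adjust(pers$p)
  pers$significant <- !is.na(pers$p_fdr) & pers$p_fdr < q
  list(pairs = pairs, persistence = pers)
}

#' Full transition analysis for one group
#'
#' Convenience wrapper: counts, persistence, transition probabilities,
#' surrogate ensemble, pathway significance and directionality test.
#'
#' @param sequences list of per-subject label sequences for the group.
#' @param K number of CAPs.
#' @param n_surrogates surrogates for the null ensemble.
#' @param seed integer seed.
#' @param q FDR level.
#' @return object of class `transition_table` with `counts`, `persistence`,
#'   `trans`, `ensemble`, `significance`, `directionality`.
#' @export
analyze_transitions <- function(sequences, K, n_surrogates = 10000L,
                                seed = 1L, q = 0.05) {
  counts <- count_transitions(sequences, K)
  persistence <- persistence_probabilities(counts)
  trans <- transition_probabilities(counts)
  ensemble <- surrogate_null(sequences, K, n_surrogates, seed)
  significance <- pair_significance(trans, ensemble, q)
  directionality <- directionality_test(trans, ensemble, significance, q)
  structure(list(counts = counts, persistence = persistence, trans = trans,
                 ensemble = ensemble, significance = significance,
                 directionality = directionality, K = as.integer(K)),
            class = "transition_table")
}

#' Edge list of a transition analysis
#'
#' @param table an [analyze_transitions()] result.
#' @return data.frame (i, j, p_ij, p_raw, p_fdr, significant, directional)
#'   for all ordered non-self pairs, ready for a schematic.
#' @export
transition_edge_list <- function(table) {
  K <- table$K
  dir_sig <- matrix(FALSE, K, K)
  d <- table$directionality
  if (nrow(d))
    dir_sig[cbind(d$from[d$significant], d$to[d$significant])] <- TRUE
  idx <- which(row(table$trans) != col(table$trans))
  data.frame(i = row(table$trans)[idx], j = col(table$trans)[idx],
             p_ij = table$trans[idx],
             p_raw = table$significance$p_raw[idx],
             p_fdr = table$significance$p_fdr[idx],
             significant = table$significance$significant[idx],
             directional = dir_sig[idx])
}
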