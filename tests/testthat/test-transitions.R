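# transition analysis: counts, persistence, p_ij, surrogate nulls,
# directionality and inter-group tests

test_that("hand-enumerated sequence gives the stated probabilities", {
  seqs <- list(c(1, 1, 2, 2, 2, 1, 3))
  counts <- count_transitions(seqs, 3)
  # pairs: (1,1),(1,2),(2,2),(2,2),(2,1),(1,3)
  expect_equal(counts, rbind(c(1, 1, 1), c(1, 2, 0), c(0, 0, 0)))
  pers <- persistence_probabilities(counts)
  expect_equal(pers[1], 1 / 3)
  expect_equal(pers[2], 2 / 3)
  expect_true(is.na(pers[3]))                      # no outgoing transitions
  p <- transition_probabilities(counts)
  expect_equal(p[1, 2], 1 / 2)
  expect_equal(p[1, 3], 1 / 2)
  expect_equal(p[2, 1], 1)
  expect_true(all(is.na(diag(p))))
})

test_that("boundary rules: single frames and subject breaks", {
  expect_equal(sum(count_transitions(list(1L), 3)), 0)
  counts <- count_transitions(list(c(1L, 2L), c(2L, 1L)), 3)
  expect_equal(counts[1, 2], 1)
  expect_equal(counts[2, 1], 1)
  expect_equal(sum(counts), 2)                     # no cross-subject pair
  expect_error(count_transitions(list(c(1L, 5L)), 3), "outside")
  # deterministic cycle
  cyc <- count_transitions(list(rep(c(1L, 2L, 3L), 20)), 3)
  p <- transition_probabilities(cyc)
  expect_equal(p[1, 2], 1); expect_equal(p[2, 3], 1); expect_equal(p[3, 1], 1)
  expect_equal(p[1, 3], 0)
  # constant sequence: persistence 1
  expect_equal(persistence_probabilities(
    count_transitions(list(rep(2L, 10)), 3))[2], 1)
})

test_that("counts and probabilities match the oracle exhaustively (L <= 6)", {
  for (L in 2:6) {
    for (s in all_sequences(3, L)) {
      counts <- count_transitions(list(s), 3)
      expect_equal(counts, oracle_count_transitions(list(s), 3),
                   tolerance = 0)
    }
  }
  # row normalization: defined rows of p sum to 1 exactly
  s <- with_seed(60, sample.int(4, 500, replace = TRUE))
  p <- transition_probabilities(count_transitions(list(s), 4))
  expect_equal(rowSums(p, na.rm = TRUE), rep(1, 4), tolerance = 1e-12)
})

test_that("planted chains are estimated at the stated precision", {
  mk <- uniform_persistence_markov(6, 0.85)
  seqs <- lapply(1:10, function(i) generate_state_sequence(mk, 980, 70 + i))
  counts <- count_transitions(seqs, 6)
  expect_true(all(abs(persistence_probabilities(counts) - 0.85) < 0.02))
  p <- transition_probabilities(counts)
  expect_lt(max(abs(p - 0.2), na.rm = TRUE), 0.05)
})

test_that("surrogates preserve label multisets and are calibrated", {
  # length-2 sequence: the two permutations appear about equally often
  ens <- surrogate_null(list(c(1L, 2L)), 2, n_surrogates = 2000, seed = 3)
  frac_12 <- mean(!is.na(ens$trans[, 1, 2]))
  expect_lt(abs(frac_12 - 0.5), 0.05)
  # multiset preservation: pooled counts per surrogate always total T - 1
  seqs <- list(c(1L, 1L, 2L, 3L, 2L), c(3L, 3L, 1L))
  expect_warning(ens2 <- surrogate_null(seqs, 3, n_surrogates = 50, seed = 4),
                 "resolution")
  # determinism under seed
  ens3 <- suppressWarnings(surrogate_null(seqs, 3, n_surrogates = 50, seed = 4))
  expect_identical(ens2$trans, ens3$trans)
  # i.i.d. null: observed p_ij inside the central 95% about 95% of the time
  hits <- 0L; n_checks <- 0L
  for (r in 1:25) {
    s <- with_seed(800 + r, sample.int(3, 400, replace = TRUE))
    obs <- transition_probabilities(count_transitions(list(s), 3))
    e <- surrogate_null(list(s), 3, n_surrogates = 400, seed = 900 + r)
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      q <- stats::quantile(e$trans[, i, j], c(0.025, 0.975), na.rm = TRUE)
      hits <- hits + (obs[i, j] >= q[1] && obs[i, j] <= q[2])
      n_checks <- n_checks + 1L
    }
  }
  expect_gt(hits / n_checks, 0.88)
})

test_that("extreme observations get the stated add-one p-values", {
  # observed above every surrogate -> p = 1 / (n + 1)
  K <- 2
  obs <- matrix(c(NA, 1, 1, NA), 2, 2)
  ens <- list(trans = array(0.2, c(100, 2, 2)), persist = NULL,
              n_surrogates = 100L)
  sig <- pair_significance(obs, ens)
  expect_equal(sig$p_raw[1, 2], 1 / 101)
  # observed below every surrogate -> p = 1
  obs0 <- matrix(c(NA, 0, 0, NA), 2, 2)
  sig0 <- pair_significance(obs0, ens)
  expect_equal(sig0$p_raw[1, 2], 1)
})

test_that("directionality is antisymmetric and detects planted asymmetry", {
  tr <- matrix(0.15 * 0.2, 6, 6); diag(tr) <- 0.85
  tr[1, 2:6] <- 0.15 * c(0.6, rep(0.1, 4))
  tr[2, c(1, 3:6)] <- 0.15 * rep(0.2, 5)
  mk <- markov_spec(tr)
  seqs <- lapply(1:10, function(i) generate_state_sequence(mk, 980, 200 + i))
  tab <- analyze_transitions(seqs, 6, n_surrogates = 1000, seed = 5)
  expect_true(tab$significance$significant[1, 2])
  d <- tab$directionality
  row12 <- d[d$from == 1 & d$to == 2, ]
  expect_equal(nrow(row12), 1)
  expect_true(row12$significant)
  expect_equal(row12$d,
               tab$trans[1, 2] - tab$trans[2, 1], tolerance = 1e-12)
  # the reverse orientation is never tested twice: antisymmetry by design
  expect_equal(nrow(d[d$from == 2 & d$to == 1, ]), 0)
})

test_that("identical groups yield zero deltas with p about 1", {
  mk <- uniform_persistence_markov(4, 0.8)
  seqs <- lapply(1:4, function(i) generate_state_sequence(mk, 400, 300 + i))
  counts <- count_transitions(seqs, 4)
  obs <- transition_probabilities(counts)
  pers <- persistence_probabilities(counts)
  ens_a <- surrogate_null(seqs, 4, 500, seed = 6)
  ens_b <- surrogate_null(seqs, 4, 500, seed = 7)
  sig <- pair_significance(obs, ens_a)
  res <- intergroup_difference_test(obs, obs, ens_a, ens_b, sig, sig,
                                    pers, pers)
  if (nrow(res$pairs)) {
    expect_true(all(res$pairs$delta == 0))
    expect_true(all(res$pairs$p == 1))
  }
  expect_true(all(res$persistence$delta == 0))
  expect_true(all(res$persistence$p == 1))
  # swapping the groups flips every delta's sign
  mk2 <- uniform_persistence_markov(4, 0.6)
  seqs2 <- lapply(1:4, function(i) generate_state_sequence(mk2, 400, 400 + i))
  counts2 <- count_transitions(seqs2, 4)
  obs2 <- transition_probabilities(counts2)
  pers2 <- persistence_probabilities(counts2)
  ens2 <- surrogate_null(seqs2, 4, 500, seed = 8)
  sig2 <- pair_significance(obs2, ens2)
  ab <- intergroup_difference_test(obs, obs2, ens_a, ens2, sig, sig2,
                                   pers, pers2)
  ba <- intergroup_difference_test(obs2, obs, ens2, ens_a, sig2, sig,
                                   pers2, pers)
  expect_equal(ab$persistence$delta, -ba$persistence$delta)
  if (nrow(ab$pairs))
    expect_equal(ab$pairs$delta, -ba$pairs$delta[match(
      paste(ab$pairs$from, ab$pairs$to),
      paste(ba$pairs$from, ba$pairs$to))])
})

test_that("a planted inter-group transition perturbation is detected", {
  tr_a <- matrix(0.15 * 0.25, 5, 5); diag(tr_a) <- 0.85
  tr_b <- tr_a
  tr_b[1, 2:5] <- 0.15 * c(0.5, 0.25, 0.15, 0.10)   # +0.25 on pair (1,2)
  seqs_a <- lapply(1:8, function(i)
    generate_state_sequence(markov_spec(tr_a), 980, 500 + i))
  seqs_b <- lapply(1:8, function(i)
    generate_state_sequence(markov_spec(tr_b), 980, 600 + i))
  ca <- count_transitions(seqs_a, 5); cb <- count_transitions(seqs_b, 5)
  oa <- transition_probabilities(ca); ob <- transition_probabilities(cb)
  ea <- surrogate_null(seqs_a, 5, 1000, seed = 9)
  eb <- surrogate_null(seqs_b, 5, 1000, seed = 10)
  sa <- pair_significance(oa, ea); sb <- pair_significance(ob, eb)
  res <- intergroup_difference_test(ob, oa, eb, ea, sb, sa,
                                    persistence_probabilities(cb),
                                    persistence_probabilities(ca))
  hit <- res$pairs[res$pairs$from == 1 & res$pairs$to == 2, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$significant)
  expect_gt(hit$delta, 0.15)
})

test_that("the edge list covers all ordered non-self pairs", {
  mk <- uniform_persistence_markov(6, 0.85)
  seqs <- lapply(1:4, function(i) generate_state_sequence(mk, 500, 700 + i))
  tab <- analyze_transitions(seqs, 6, n_surrogates = 200, seed = 11)
  el <- transition_edge_list(tab)
  expect_equal(nrow(el), 30)                        # 6 x 5 ordered pairs
  expect_true(all(el$i != el$j))
})
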