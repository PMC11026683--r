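#include <Rcpp.h>
using namespace Rcpp;

// Pooled transition counts for one pass over a set of label sequences.
// Consecutive pairs are counted within each sequence only; nothing spans
// a subject boundary.
static void count_pairs(const std::vector<std::vector<int>>& seqs, int K,
                        std::vector<double>& counts) {
  std::fill(counts.begin(), counts.end(), 0.0);
  for (const auto& s : seqs) {
    for (size_t t = 1; t < s.size(); ++t) {
      counts[(s[t - 1] - 1) * K + (s[t] - 1)] += 1.0;
    }
  }
}

// persistence_i = c(i,i) / rowsum_i; p_ij = c(i,j) / (rowsum_i - c(i,i)).
// Undefined entries become NaN.
static void probs_from_counts(const std::vector<double>& counts, int K,
                              double* persist, double* trans) {
  for (int i = 0; i < K; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < K; ++j) rowsum += counts[i * K + j];
    double self = counts[i * K + i];
    persist[i] = rowsum > 0 ? self / rowsum : NA_REAL;
    double nonself = rowsum - self;
    for (int j = 0; j < K; ++j) {
      if (i == j) { trans[i * K + j] = NA_REAL; continue; }
      trans[i * K + j] = nonself > 0 ? counts[i * K + j] / nonself : NA_REAL;
    }
  }
}

// Surrogate ensemble: for each surrogate, every subject's label sequence is
// permuted uniformly at random (Fisher-Yates driven by R's RNG, so results
// are reproducible under set.seed), the group-pooled transition counts are
// recomputed, and persistence / non-self transition probabilities stored.
// [[Rcpp::export]]
List surrogate_ensemble_cpp(List sequences, int K, int n_surrogates) {
  size_t n_subj = sequences.size();
  std::vector<std::vector<int>> seqs(n_subj);
  for (size_t s = 0; s < n_subj; ++s) {
    IntegerVector v = sequences[s];
    seqs[s] = std::vector<int>(v.begin(), v.end());
  }
  NumericVector trans(n_surrogates * K * K);
  NumericMatrix persist(n_surrogates, K);
  std::vector<double> counts(K * K);
  std::vector<double> p(K), tr(K * K);

  RNGScope scope;
  for (int r = 0; r < n_surrogates; ++r) {
    for (auto& s : seqs) {
      for (size_t i = s.size() - 1; i > 0; --i) {
        size_t j = (size_t)(unif_rand() * (i + 1));
        if (j > i) j = i;  // guard against unif_rand() == 1.0
        std::swap(s[i], s[j]);
      }
    }
    count_pairs(seqs, K, counts);
    probs_from_counts(counts, K, p.data(), tr.data());
    for (int i = 0; i < K; ++i) {
      persist(r, i) = p[i];
      for (int j = 0; j < K; ++j) {
        // layout: [surrogate, i, j] in an n x K x K array (column-major)
        trans[r + n_surrogates * (i + K * j)] = tr[i * K + j];
      }
    }
  }
  trans.attr("dim") = IntegerVector::create(n_surrogates, K, K);
  return List::create(_["trans"] = trans, _["persist"] = persist);
}

// Exact pooled transition counts, exposed for the R-level observed path.
// [[Rcpp::export]]
NumericMatrix count_transitions_cpp(List sequences, int K) {
  size_t n_subj = sequences.size();
  std::vector<std::vector<int>> seqs(n_subj);
  for (size_t s = 0; s < n_subj; ++s) {
    IntegerVector v = sequences[s];
    seqs[s] = std::vector<int>(v.begin(), v.end());
  }
  std::vector<double> counts(K * K);
  count_pairs(seqs, K, counts);
  NumericMatrix out(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) out(i, j) = counts[i * K + j];
  return out;
}
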