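#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling where the input representation of a word
// is the SUM of its piece vectors (the word itself plus, optionally, its
// boundary-marked character n-grams), so unseen words can later be composed
// from known n-grams. Single-threaded and fully deterministic given seed.
//
// docs:   list of 0-based word-id vectors
// pieces: list (length n_words) of 0-based piece ids per word
// freq:   corpus frequency per word id (negative-sampling distribution ^0.75)
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List docs, List pieces, int n_pieces, int dim,
                             int window, int epochs, int negative,
                             double lr0, NumericVector freq,
                             unsigned int seed) {
  const int n_words = freq.size();
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<std::vector<int>> pc(n_words);
  for (int wid = 0; wid < n_words; ++wid) {
    IntegerVector pv = pieces[wid];
    pc[wid].assign(pv.begin(), pv.end());
  }

  // cumulative table for unigram^0.75 negative sampling
  std::vector<double> cum(n_words);
  double tot = 0.0;
  for (int wid = 0; wid < n_words; ++wid) {
    tot += std::pow(freq[wid], 0.75);
    cum[wid] = tot;
  }

  NumericMatrix in(n_pieces, dim);   // piece vectors
  std::vector<double> out((size_t)n_words * dim, 0.0);
  for (int i = 0; i < n_pieces; ++i)
    for (int j = 0; j < dim; ++j)
      in(i, j) = (unif(rng) - 0.5) / dim;

  long long total_tokens = 0;
  for (int d = 0; d < docs.size(); ++d)
    total_tokens += ((IntegerVector)docs[d]).size();
  const long long total_updates = total_tokens * (long long)epochs;
  long long done = 0;

  std::vector<double> h(dim), dh(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      const int n = doc.size();
      for (int i = 0; i < n; ++i) {
        double lr = lr0 * (1.0 - (double)done / (double)(total_updates + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++done;
        int b = 1 + (int)(unif(rng) * window);
        if (b > window) b = window;
        const int center = doc[i];
        const std::vector<int>& cp = pc[center];
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          // compose center hidden vector
          std::fill(h.begin(), h.end(), 0.0);
          std::fill(dh.begin(), dh.end(), 0.0);
          for (int p : cp)
            for (int c = 0; c < dim; ++c) h[c] += in(p, c);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = doc[j]; label = 1.0; }
            else {
              double r = unif(rng) * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) -
                             cum.begin());
              if (target >= n_words) target = n_words - 1;
              if (target == doc[j]) continue;
              label = 0.0;
            }
            double* ov = &out[(size_t)target * dim];
            double f = 0.0;
            for (int c = 0; c < dim; ++c) f += h[c] * ov[c];
            f = 1.0 / (1.0 + std::exp(-f));
            const double g = lr * (label - f);
            for (int c = 0; c < dim; ++c) {
              dh[c] += g * ov[c];
              ov[c] += g * h[c];
            }
          }
          for (int p : cp)
            for (int c = 0; c < dim; ++c) in(p, c) += dh[c];
        }
      }
    }
  }
  return in;
}
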