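#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for smoothed LDA.
// docs: list of 0-based word-id integer vectors; empty docs allowed (skipped).
// Returns topic-word counts (phi source) and averaged document-topic
// proportions over the post-burn-in passes.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int n_vocab, int n_topics,
                   double alpha, double eta, int passes, int burnin,
                   unsigned int seed) {
  const int D = docs.size();
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<std::vector<int>> w(D), z(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector wd = docs[d];
    w[d].assign(wd.begin(), wd.end());
    z[d].resize(wd.size());
  }

  NumericMatrix ndk(D, n_topics);      // doc-topic counts
  NumericMatrix nkw(n_topics, n_vocab);  // topic-word counts
  std::vector<double> nk(n_topics, 0.0);

  // random initial assignment
  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif(rng) * n_topics);
      if (k == n_topics) k = n_topics - 1;
      z[d][i] = k;
      ndk(d, k) += 1.0; nkw(k, w[d][i]) += 1.0; nk[k] += 1.0;
    }
  }

  NumericMatrix theta_acc(D, n_topics);
  int n_acc = 0;
  std::vector<double> p(n_topics);
  const double Veta = n_vocab * eta;

  for (int pass = 0; pass < passes; ++pass) {
    for (int d = 0; d < D; ++d) {
      const size_t nd = w[d].size();
      for (size_t i = 0; i < nd; ++i) {
        const int word = w[d][i];
        const int old = z[d][i];
        ndk(d, old) -= 1.0; nkw(old, word) -= 1.0; nk[old] -= 1.0;
        double tot = 0.0;
        for (int k = 0; k < n_topics; ++k) {
          p[k] = (ndk(d, k) + alpha) * (nkw(k, word) + eta) / (nk[k] + Veta);
          tot += p[k];
        }
        double r = unif(rng) * tot, cum = 0.0;
        int knew = n_topics - 1;
        for (int k = 0; k < n_topics; ++k) {
          cum += p[k];
          if (r <= cum) { knew = k; break; }
        }
        z[d][i] = knew;
        ndk(d, knew) += 1.0; nkw(knew, word) += 1.0; nk[knew] += 1.0;
      }
    }
    if (pass >= burnin) {
      for (int d = 0; d < D; ++d) {
        const double denom = (double)w[d].size() + n_topics * alpha;
        for (int k = 0; k < n_topics; ++k)
          theta_acc(d, k) += (ndk(d, k) + alpha) / denom;
      }
      ++n_acc;
    }
  }
  if (n_acc > 0)
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < n_topics; ++k) theta_acc(d, k) /= n_acc;

  return List::create(_["topic_word"] = nkw, _["theta"] = theta_acc);
}
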