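#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic RNG independent of R's RNG stream, so training is
// bit-reproducible for a given seed regardless of the caller's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { int v = (int)(unif() * n); return v >= n ? n - 1 : v; }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling, single-threaded.
// sentences: list of integer vectors of 0-based vocabulary ids.
// counts: token frequencies per vocabulary id (for the noise distribution,
// raised to the 3/4 power as is standard).
// Returns the input-vector matrix, vocab x dim.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, IntegerVector counts, int dim,
                             int window, int epochs, int negative,
                             double alpha, double min_alpha, int seed) {
  const int vocab = counts.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)vocab * dim);
  std::vector<double> syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 noise table
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double norm = 0.0;
  for (int v = 0; v < vocab; ++v) norm += std::pow((double)counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow((double)counts[0], 0.75) / norm;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((double)(t + 1) / table_size > cum && v < vocab - 1) {
        ++v;
        cum += std::pow((double)counts[v], 0.75) / norm;
      }
    }
  }

  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_words += (long long)((IntegerVector)sentences[s]).size();
  total_words *= epochs;
  if (total_words == 0) stop("empty corpus");

  std::vector<double> grad(dim);
  long long seen = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        ++seen;
        double lr = alpha - (alpha - min_alpha) * ((double)seen / total_words);
        if (lr < min_alpha) lr = min_alpha;
        const int center = sent[pos];
        const int reduced = rng.below(window) + 1;  // dynamic window
        for (int off = -reduced; off <= reduced; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int context = sent[cpos];
          double* v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) grad[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
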