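// Negative-sampling skip-gram SGD. Single-threaded with a private
// deterministic RNG so that corpus + config + seed fully determine the
// resulting vectors, independent of R's RNG state.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) {
    // splitmix64 scramble so small seeds give well-mixed states
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int bounded(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoidd(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// input_t / output_t are d x W (one column per token, contiguous).
// toks: 0-based token indices of all sentences concatenated;
// offsets: length n_sent + 1 cumulative sentence boundaries.
// [[Rcpp::export]]
List sg_train_ns_cpp(NumericMatrix input_t, NumericMatrix output_t,
                     IntegerVector toks, IntegerVector offsets,
                     NumericVector counts, int window, int negative,
                     int epochs, double lr, double lr_min, int seed,
                     bool dynamic_window) {
  const int d = input_t.nrow();
  const int W = input_t.ncol();
  const int n_sent = offsets.size() - 1;

  NumericMatrix syn0(clone(input_t));
  NumericMatrix syn1(clone(output_t));
  double *s0 = REAL(syn0), *s1 = REAL(syn1);

  // cumulative unigram^{3/4} noise table, sampled by binary search
  std::vector<double> cum(W);
  double tot = 0.0;
  for (int w = 0; w < W; ++w) {
    tot += std::pow(counts[w], 0.75);
    cum[w] = tot;
  }

  XorShift64 rng(static_cast<uint64_t>(seed));
  std::vector<double> neu1e(d);

  const long long total_pos =
      static_cast<long long>(toks.size()) * epochs;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const int lo = offsets[s], hi = offsets[s + 1];
      for (int t = lo; t < hi; ++t) {
        double alpha = lr - (lr - lr_min) *
            (static_cast<double>(processed) / static_cast<double>(total_pos));
        ++processed;
        const int center = toks[t];
        double *vc = s0 + static_cast<size_t>(center) * d;
        const int b = dynamic_window ? 1 + rng.bounded(window) : window;
        for (int j = -b; j <= b; ++j) {
          if (j == 0) continue;
          const int u = t + j;
          if (u < lo || u >= hi) continue;
          const int pos_target = toks[u];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) {
              target = pos_target; label = 1.0;
            } else {
              double r = rng.unif() * tot;
              target = static_cast<int>(
                  std::upper_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= W) target = W - 1;
              if (target == pos_target) continue;
              label = 0.0;
            }
            double *vo = s1 + static_cast<size_t>(target) * d;
            double f = 0.0;
            for (int i = 0; i < d; ++i) f += vc[i] * vo[i];
            const double g = (label - sigmoidd(f)) * alpha;
            for (int i = 0; i < d; ++i) neu1e[i] += g * vo[i];
            for (int i = 0; i < d; ++i) vo[i] += g * vc[i];
          }
          for (int i = 0; i < d; ++i) vc[i] += neu1e[i];
        }
      }
    }
  }

  return List::create(Named("input") = syn0, Named("output") = syn1);
}
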