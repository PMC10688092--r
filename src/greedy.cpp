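#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Restarted stochastic greedy minimisation of the penalized weighted
// least-squares segmentation loss
//   L = sum_s sum_{i in s} w_i (x_i - xbar_s)^2 + lambda * |S|
// with weighted per-segment means xbar_s. Breakpoints are "cuts" c in
// 1..n-1 (0-based: after data index c-1). Fixed cuts (from an earlier
// segmentation pass) are always present and can be neither removed nor
// shifted. Every segment must span at least min_span bp (positions are the
// per-point genomic extents); the single whole-arm segment is always
// admissible.
//
// Each restart starts from the fixed-cuts-only solution and repeatedly
// proposes one random move (add a cut at a random admissible position,
// remove a random free cut, or shift a random free cut by one data point),
// accepting only strict decreases of L, and stops after 100 consecutive
// rejections. The best configuration over all restarts is returned. All
// randomness comes from R's RNG, so results are reproducible via set.seed.

namespace {

struct LossCalc {
  std::vector<double> cw, cwx, cwxx;  // prefix sums of w, w*x, w*x^2
  int n;
  LossCalc(const NumericVector& x, const NumericVector& w) : n(x.size()) {
    cw.resize(n + 1, 0.0);
    cwx.resize(n + 1, 0.0);
    cwxx.resize(n + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      cw[i + 1] = cw[i] + w[i];
      cwx[i + 1] = cwx[i] + w[i] * x[i];
      cwxx[i + 1] = cwxx[i] + w[i] * x[i] * x[i];
    }
  }
  // weighted SSE of the segment covering data indices [a, b) (0-based)
  double sse(int a, int b) const {
    double W = cw[b] - cw[a];
    if (W <= 0.0) return 0.0;
    double S = cwx[b] - cwx[a];
    double Q = cwxx[b] - cwxx[a];
    double v = Q - S * S / W;
    return v > 0.0 ? v : 0.0;
  }
};

int rand_int(int k) {  // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

}  // namespace

// [[Rcpp::export(name = ".greedy_segment_cpp")]]
List greedy_segment_cpp(NumericVector x, NumericVector w,
                        NumericVector pos_start, NumericVector pos_end,
                        double lambda, double min_span,
                        IntegerVector fixed_cuts, int restarts,
                        int stop_after = 100, int max_iter = 100000) {
  const int n = x.size();
  LossCalc lc(x, w);
  const bool arm_short = (pos_end[n - 1] - pos_start[0]) < min_span;

  std::vector<int> fixed(fixed_cuts.begin(), fixed_cuts.end());
  std::sort(fixed.begin(), fixed.end());
  std::vector<bool> is_fixed(n, false);
  for (int c : fixed) is_fixed[c] = true;

  // segment [a, b) admissible iff it spans min_span, or is the whole arm
  auto admissible = [&](int a, int b) {
    if (a == 0 && b == n) return true;
    if (arm_short) return false;
    return (pos_end[b - 1] - pos_start[a]) >= min_span;
  };

  auto total_loss = [&](const std::vector<int>& cuts) {
    double L = lambda * (cuts.size() + 1);
    int a = 0;
    for (int c : cuts) { L += lc.sse(a, c); a = c; }
    L += lc.sse(a, n);
    return L;
  };

  std::vector<int> best_cuts = fixed;
  double best_loss = total_loss(fixed);
  if (arm_short || n == 1) {
    // no free cut can be added
    return List::create(_["cuts"] = IntegerVector(fixed.begin(), fixed.end()),
                        _["loss"] = total_loss(fixed));
  }

  std::vector<int> cuts;
  for (int r = 0; r < restarts; ++r) {
    cuts = fixed;
    double loss = total_loss(cuts);
    int rejected = 0, iter = 0;
    while (rejected < stop_after && iter < max_iter) {
      ++iter;
      int move = rand_int(3);
      bool accepted = false;
      if (move == 0) {
        // add a cut at a random position in 1..n-1
        int c = 1 + rand_int(n - 1);
        if (!std::binary_search(cuts.begin(), cuts.end(), c)) {
          auto it = std::upper_bound(cuts.begin(), cuts.end(), c);
          int b = (it == cuts.end()) ? n : *it;
          int a = (it == cuts.begin()) ? 0 : *(it - 1);
          if (admissible(a, c) && admissible(c, b)) {
            double delta = lc.sse(a, c) + lc.sse(c, b) - lc.sse(a, b) + lambda;
            if (delta < -1e-12) {
              cuts.insert(it, c);
              loss += delta;
              accepted = true;
            }
          }
        }
      } else if (cuts.size() > fixed.size()) {
        // pick a random free cut
        int nfree = cuts.size() - fixed.size();
        int pick = rand_int(nfree), seen = -1, ci = -1;
        for (int i = 0; i < (int)cuts.size(); ++i) {
          if (!is_fixed[cuts[i]]) {
            if (++seen == pick) { ci = i; break; }
          }
        }
        int c = cuts[ci];
        int a = (ci == 0) ? 0 : cuts[ci - 1];
        int b = (ci + 1 == (int)cuts.size()) ? n : cuts[ci + 1];
        if (move == 1) {
          // remove
          if (admissible(a, b)) {
            double delta = lc.sse(a, b) - lc.sse(a, c) - lc.sse(c, b) - lambda;
            if (delta < -1e-12) {
              cuts.erase(cuts.begin() + ci);
              loss += delta;
              accepted = true;
            }
          }
        } else {
          // shift by one data point
          int c2 = c + (unif_rand() < 0.5 ? -1 : 1);
          if (c2 > a && c2 < b && c2 >= 1 && c2 <= n - 1 &&
              admissible(a, c2) && admissible(c2, b)) {
            double delta = lc.sse(a, c2) + lc.sse(c2, b)
                         - lc.sse(a, c) - lc.sse(c, b);
            if (delta < -1e-12) {
              cuts[ci] = c2;
              loss += delta;
              accepted = true;
            }
          }
        }
      }
      rejected = accepted ? 0 : rejected + 1;
    }
    if (loss < best_loss - 1e-12) {
      best_loss = loss;
      best_cuts = cuts;
    }
  }
  return List::create(_["cuts"] = IntegerVector(best_cuts.begin(), best_cuts.end()),
                      _["loss"] = best_loss);
}
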