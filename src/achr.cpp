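#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Artificial-centering hit-and-run chain over the flux polytope
// {x : S x = 0, lb <= x <= ub}. Directions are differences between stored
// points (warmup + running center), so every iterate stays in the affine
// null space of S; only the box bounds need line-search. Uses R's RNG, so
// set.seed() makes the chain bit-reproducible.
//
// warmup: n_dim x n_warm matrix of feasible points (FVA vertices)
// x0:     feasible starting point (e.g. warmup mean)
// Returns n_samples x n_dim matrix keeping every `thinning`-th state.
// [[Rcpp::export(name = ".achrChain")]]
NumericMatrix achr_chain(NumericMatrix warmup, NumericVector x0,
                         NumericVector lb, NumericVector ub,
                         int n_samples, int thinning) {
  const int n = x0.size();
  const int W = warmup.ncol();
  const double tol = 1e-12;
  std::vector<double> center(n, 0.0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < n; ++i) center[i] += warmup(i, j);
  for (int i = 0; i < n; ++i) center[i] /= W;
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = x0[i];
  NumericMatrix out(n_samples, n);
  std::vector<double> d(n);
  long long total = (long long)n_samples * (long long)thinning;
  long long seen = W;  // points absorbed into the running center
  int kept = 0;
  for (long long step = 0; step < total; ++step) {
    // direction through the current center from a random stored point
    int j = (int)(unif_rand() * W);
    if (j >= W) j = W - 1;
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) {
      d[i] = warmup(i, j) - center[i];
      nrm += d[i] * d[i];
    }
    nrm = std::sqrt(nrm);
    double amin = -std::numeric_limits<double>::infinity();
    double amax = std::numeric_limits<double>::infinity();
    if (nrm > tol) {
      for (int i = 0; i < n; ++i) {
        if (std::fabs(d[i]) <= tol) continue;
        double lo = (lb[i] - x[i]) / d[i];
        double hi = (ub[i] - x[i]) / d[i];
        if (d[i] > 0) {
          if (lo > amin) amin = lo;
          if (hi < amax) amax = hi;
        } else {
          if (hi > amin) amin = hi;
          if (lo < amax) amax = lo;
        }
      }
      if (std::isfinite(amin) && std::isfinite(amax) && amax > amin) {
        double alpha = amin + unif_rand() * (amax - amin);
        for (int i = 0; i < n; ++i) {
          x[i] += alpha * d[i];
          if (x[i] < lb[i]) x[i] = lb[i];
          if (x[i] > ub[i]) x[i] = ub[i];
        }
      }
    }
    // artificial centering: fold the iterate into the running center
    for (int i = 0; i < n; ++i)
      center[i] = (center[i] * seen + x[i]) / (seen + 1);
    ++seen;
    if ((step + 1) % thinning == 0) {
      for (int i = 0; i < n; ++i) out(kept, i) = x[i];
      ++kept;
    }
  }
  return out;
}
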