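#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <limits>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Affinity propagation by damped responsibility/availability message
// passing. Deterministic: no random initialization; a tiny deterministic,
// input-independent perturbation (hash of the cell index, ~1e-9 of the
// similarity range) breaks exact ties so degenerate oscillations settle;
// remaining argmax ties go to the lowest index. Convergence = exemplar
// decision vector unchanged for `convits` consecutive iterations.
// [[Rcpp::export]]
List ap_cluster_cpp(NumericMatrix S, double preference, double damping,
                    int maxit, int convits) {
  const int n = S.nrow();
  std::vector<double> s(n * n);        // s[k + n*i] = S(i,k) + jitter
  double smin = R_PosInf, smax = R_NegInf;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n; ++k) {
      double v = (i == k) ? preference : S(i, k);
      if (v < smin) smin = v;
      if (v > smax) smax = v;
    }
  const double delta = (smax - smin) * 1e-9;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n; ++k) {
      uint32_t h = (uint32_t)(i * 2654435761u + k * 40503u);
      double jit = delta * ((h % 1024u) / 1024.0 - 0.5);
      s[k + (size_t)n * i] = ((i == k) ? preference : S(i, k)) + jit;
    }

  std::vector<double> Rm(n * n, 0.0);  // Rm[k + n*i] = R(i,k)
  std::vector<double> Am(n * n, 0.0);  // Am[k + n*i] = A(i,k)
  std::vector<double> sp(n), rkk(n);
  std::vector<int> decided(n, 0), last(n, -1);
  int stable = 0, it = 0;
  bool converged = false;
  const double ninf = -std::numeric_limits<double>::infinity();

  for (it = 0; it < maxit; ++it) {
    // responsibilities: R(i,k) <- s(i,k) - max_{k'!=k} (A(i,k') + s(i,k'))
    for (int i = 0; i < n; ++i) {
      const double *si = &s[(size_t)n * i];
      const double *ai = &Am[(size_t)n * i];
      double *ri = &Rm[(size_t)n * i];
      double max1 = ninf, max2 = ninf;
      int arg1 = -1;
      for (int k = 0; k < n; ++k) {
        double v = ai[k] + si[k];
        if (v > max1) { max2 = max1; max1 = v; arg1 = k; }
        else if (v > max2) max2 = v;
      }
      for (int k = 0; k < n; ++k) {
        double rnew = si[k] - (k == arg1 ? max2 : max1);
        ri[k] = damping * ri[k] + (1.0 - damping) * rnew;
      }
    }
    // availabilities: sp[k] = sum_{i!=k} max(0, R(i,k)), rkk[k] = R(k,k)
    std::fill(sp.begin(), sp.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double *ri = &Rm[(size_t)n * i];
      for (int k = 0; k < n; ++k)
        if (k != i && ri[k] > 0.0) sp[k] += ri[k];
      rkk[i] = ri[i];
    }
    for (int i = 0; i < n; ++i) {
      const double *ri = &Rm[(size_t)n * i];
      double *ai = &Am[(size_t)n * i];
      for (int k = 0; k < n; ++k) {
        double anew;
        if (i == k) {
          anew = sp[k];
        } else {
          double v = rkk[k] + sp[k] - (ri[k] > 0.0 ? ri[k] : 0.0);
          anew = v < 0.0 ? v : 0.0;
        }
        ai[k] = damping * ai[k] + (1.0 - damping) * anew;
      }
    }
    // exemplar decisions
    bool same = true;
    int ndec = 0;
    for (int k = 0; k < n; ++k) {
      decided[k] = (Am[k + (size_t)n * k] + Rm[k + (size_t)n * k] > 0.0) ? 1 : 0;
      ndec += decided[k];
      if (decided[k] != last[k]) same = false;
      last[k] = decided[k];
    }
    if (same) {
      if (++stable >= convits && ndec > 0) { converged = true; break; }
    } else {
      stable = 0;
    }
  }

  std::vector<int> exemplars;
  for (int k = 0; k < n; ++k) if (decided[k]) exemplars.push_back(k);
  if (exemplars.empty()) {
    int best = 0;
    double bv = Am[0] + Rm[0];
    for (int k = 1; k < n; ++k) {
      double v = Am[k + (size_t)n * k] + Rm[k + (size_t)n * k];
      if (v > bv) { bv = v; best = k; }
    }
    exemplars.push_back(best);
  }

  // assign to the most similar exemplar (exemplars to themselves)
  const int ne = (int)exemplars.size();
  IntegerVector assign(n);
  auto do_assign = [&]() {
    for (int i = 0; i < n; ++i) {
      int bestk = -1;
      double bv = ninf;
      bool self = false;
      for (int e = 0; e < ne; ++e)
        if (exemplars[e] == i) { self = true; bestk = e; break; }
      if (!self)
        for (int e = 0; e < ne; ++e) {
          double v = s[exemplars[e] + (size_t)n * i];
          if (v > bv) { bv = v; bestk = e; }
        }
      assign[i] = bestk + 1;
    }
  };
  do_assign();
  // one refinement pass: within each cluster pick the member maximizing the
  // summed similarity from the other members (standard AP final step)
  for (int e = 0; e < ne; ++e) {
    double bv = ninf;
    int bestj = exemplars[e];
    for (int j = 0; j < n; ++j) {
      if (assign[j] != e + 1) continue;
      double sum = 0.0;
      for (int i = 0; i < n; ++i)
        if (assign[i] == e + 1 && i != j) sum += s[j + (size_t)n * i];
      if (sum > bv) { bv = sum; bestj = j; }
    }
    exemplars[e] = bestj;
  }
  do_assign();

  IntegerVector ex(ne);
  for (int e = 0; e < ne; ++e) ex[e] = exemplars[e] + 1;
  return List::create(_["exemplars"] = ex, _["assignments"] = assign,
                      _["k"] = ne, _["iterations"] = it + 1,
                      _["converged"] = converged);
}

// Exact preference range (one- vs two-exemplar construction): pmax is the
// largest off-diagonal similarity (yields ~n clusters); pmin = dpsim1 -
// dpsim2 where dpsim1 is the best single-exemplar total similarity and
// dpsim2 the best two-exemplar total; below pmin a single cluster is the
// optimal configuration.
// [[Rcpp::export]]
List pref_bounds_cpp(NumericMatrix S) {
  const int n = S.nrow();
  double pmax = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && S(i, j) > pmax) pmax = S(i, j);

  double dpsim1 = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < n; ++k) {
    double sum = 0.0;
    for (int i = 0; i < n; ++i) if (i != k) sum += S(i, k);
    if (sum > dpsim1) dpsim1 = sum;
  }
  double dpsim2 = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < n; ++j) {
    for (int k = j + 1; k < n; ++k) {
      double sum = 0.0;
      for (int i = 0; i < n; ++i) {
        if (i == j || i == k) continue;
        sum += std::max(S(i, j), S(i, k));
      }
      if (sum > dpsim2) dpsim2 = sum;
    }
  }
  return List::create(_["pmin"] = dpsim1 - dpsim2, _["pmax"] = pmax);
}
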