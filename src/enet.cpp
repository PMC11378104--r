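#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net on standardized predictors.
// Xs: n x p, columns with mean 0 and (1/n)-variance 1; yc: centred response.
// Minimizes (1/2n)||yc - Xs b||^2 + lambda * (alpha ||b||_1 +
// (1-alpha)/2 ||b||_2^2) along a decreasing lambda path with warm starts.
// Returns p x L coefficient matrix (standardized scale).
// [[Rcpp::export]]
NumericMatrix enet_cd_path(NumericMatrix Xs, NumericVector yc, double alpha,
                           NumericVector lambdas, double tol, int max_iter) {
  const int n = Xs.nrow(), p = Xs.ncol(), L = lambdas.size();
  NumericMatrix B(p, L);
  std::vector<double> b(p, 0.0), r(yc.begin(), yc.end());
  std::vector<int> active;
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha, denom = 1.0 + lam * (1.0 - alpha);
    auto sweep = [&](const std::vector<int>& idx) {
      double max_delta = 0.0;
      for (int j : idx) {
        const double* xj = &Xs(0, j);
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
        const double z = dot / n + b[j];
        const double bj = soft(z, l1) / denom;
        const double diff = b[j] - bj;
        if (diff != 0.0) {
          for (int i = 0; i < n; ++i) r[i] += xj[i] * diff;
          b[j] = bj;
          if (std::abs(diff) > max_delta) max_delta = std::abs(diff);
        }
      }
      return max_delta;
    };
    std::vector<int> all(p);
    for (int j = 0; j < p; ++j) all[j] = j;
    int used = 0;
    // alternate: full sweep to refresh the active set, then iterate on it
    while (used < max_iter) {
      double d = sweep(all);
      ++used;
      if (d < tol) break;
      active.clear();
      for (int j = 0; j < p; ++j) if (b[j] != 0.0) active.push_back(j);
      while (used < max_iter) {
        double da = sweep(active);
        ++used;
        if (da < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) B(j, l) = b[j];
  }
  return B;
}

// Harrell concordance with per-subject pair bookkeeping. A pair (i, j) is
// usable iff the earlier observed time is an event; equal times with both
// events are unusable. Tied risk scores count 0.5.
// [[Rcpp::export]]
List harrell_c_cpp(NumericVector score, NumericVector time,
                   IntegerVector event) {
  const int n = score.size();
  NumericVector conc(n), usable(n);
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int a = -1, b = -1;  // a: earlier subject, must be an event
      if (time[i] < time[j]) { a = i; b = j; }
      else if (time[j] < time[i]) { a = j; b = i; }
      else {
        // equal times: usable only if exactly one is an event
        if (event[i] + event[j] == 1) { a = event[i] ? i : j; b = event[i] ? j : i; }
        else continue;
        // equal-time usable pair: higher score for the event counts as concordant
      }
      if (!event[a]) continue;
      double c;
      if (score[a] > score[b]) c = 1.0;
      else if (score[a] < score[b]) c = 0.0;
      else c = 0.5;
      num += c; den += 1.0;
      conc[a] += c; conc[b] += c;
      usable[a] += 1.0; usable[b] += 1.0;
    }
  }
  double C = den > 0 ? num / den : NA_REAL;
  return List::create(_["C"] = C, _["n_usable_pairs"] = den,
                      _["conc"] = conc, _["usable"] = usable);
}
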