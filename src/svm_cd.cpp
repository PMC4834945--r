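#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss SVM (Hsieh et al. 2008, the
// liblinear "L2R_L1LOSS_SVC_DUAL" solver).  Two variants: an explicit-feature
// linear solver (bias handled by an appended constant feature, so the bias is
// regularized) and a precomputed-kernel solver with warm starts along an
// increasing C path.  Iteration caps keep the cost bounded at any C, which
// SMO-based solvers do not guarantee for C as large as 1e8.

namespace {

// Minimal deterministic LCG so permutations do not touch R's RNG.
struct Lcg {
  uint64_t s;
  explicit Lcg(uint64_t seed) : s(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  uint64_t next() { s = s * 6364136223846793005ULL + 1442695040888963407ULL; return s >> 33; }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

void shuffle_idx(std::vector<int>& idx, Lcg& rng) {
  for (int i = static_cast<int>(idx.size()) - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

} // namespace

// Linear L1-loss SVM dual CD.  X is n x p (a bias column, if wanted, must be
// appended by the caller); y in {-1, +1}.  Returns the primal weight vector.
// [[Rcpp::export(name = ".cpp_linsvm_cd")]]
List cpp_linsvm_cd(NumericMatrix X, NumericVector y, double C,
                   double eps, int max_epochs, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Lcg rng(static_cast<uint64_t>(seed) + 7ULL);

  bool converged = false;
  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    shuffle_idx(idx, rng);
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (PG != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          alpha[i] = a_new;
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        }
      }
    }
    if (max_viol < eps) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch + 1,
                      _["converged"] = converged);
}

// Kernel L1-loss SVM dual CD on a precomputed Gram matrix K (n x n; a
// regularized bias is obtained by passing K + 1).  Solves for every C in the
// increasing path `Cs`, warm-starting each solve from the previous solution.
// Returns an n x length(Cs) matrix of alpha (box-constrained duals).
// [[Rcpp::export(name = ".cpp_ksvm_cd_path")]]
List cpp_ksvm_cd_path(NumericMatrix K, NumericVector y, NumericVector Cs,
                      double eps, int max_epochs, int seed) {
  const int n = K.nrow(), m = Cs.size();
  NumericMatrix A(n, m);
  std::vector<double> alpha(n, 0.0), g(n, -1.0); // g_i = sum_j Q_ij alpha_j - 1
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Lcg rng(static_cast<uint64_t>(seed) + 13ULL);
  IntegerVector epochs_used(m);
  LogicalVector conv(m);

  for (int c = 0; c < m; ++c) {
    const double C = Cs[c];
    bool converged = false;
    int epoch = 0;
    for (; epoch < max_epochs; ++epoch) {
      shuffle_idx(idx, rng);
      double max_viol = 0.0;
      for (int k = 0; k < n; ++k) {
        const int i = idx[k];
        const double qii = K(i, i);
        if (qii <= 0.0) continue;
        const double G = g[i];
        double PG = G;
        if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
        if (alpha[i] >= C && G < 0.0) PG = 0.0;
        if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
        if (PG != 0.0) {
          const double a_old = alpha[i];
          double a_new = a_old - G / qii;
          if (a_new < 0.0) a_new = 0.0;
          if (a_new > C) a_new = C;
          const double d = a_new - a_old;
          if (d != 0.0) {
            alpha[i] = a_new;
            // K is symmetric: walk column i (contiguous) instead of row i.
            const double dyi = d * y[i];
            const double* Ki = &K(0, i);
            for (int j = 0; j < n; ++j) g[j] += dyi * y[j] * Ki[j];
          }
        }
      }
      if (max_viol < eps) { converged = true; break; }
    }
    epochs_used[c] = epoch + 1;
    conv[c] = converged;
    for (int i = 0; i < n; ++i) A(i, c) = alpha[i];
  }
  return List::create(_["alpha"] = A, _["epochs"] = epochs_used,
                      _["converged"] = conv);
}
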