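#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// L2-regularized L1-loss linear SVM, solved in the dual by coordinate
// descent (Hsieh et al. 2008, the algorithm behind liblinear's -s 3).
// The bias is handled by feature augmentation (a constant-1 coordinate,
// regularized like the rest, liblinear's -B 1 convention).
//
// X is the transposed feature matrix in compressed sparse column layout:
// column j holds the feature vector of sample j (dgCMatrix slots).
// y in {-1, +1}. Per-sample cost upper bound cost[j] (C, or C * class
// weight). A private linear-congruential generator drives the epoch
// permutations so the solver is deterministic and independent of R's RNG.

static inline double col_dot_w(const int* Xi, const double* Xx,
                               int lo, int hi, const double* w) {
  double s = 0.0;
  for (int k = lo; k < hi; ++k) s += Xx[k] * w[Xi[k]];
  return s;
}

//' @noRd
// [[Rcpp::export]]
List svm_dcd_cpp(IntegerVector Xp, IntegerVector Xi, NumericVector Xx,
                 int dim, int n, NumericVector y, NumericVector cost,
                 int max_epochs, double tol, int rng_seed) {
  const int* xp = INTEGER(Xp);
  const int* xi = INTEGER(Xi);
  const double* xv = REAL(Xx);
  std::vector<double> w((size_t)dim, 0.0);
  double b = 0.0;
  std::vector<double> alpha((size_t)n, 0.0);
  std::vector<double> qii((size_t)n);
  for (int j = 0; j < n; ++j) {
    double s = 1.0;  // bias augmentation contributes 1
    for (int k = xp[j]; k < xp[j + 1]; ++k) s += xv[k] * xv[k];
    qii[j] = s;
  }
  std::vector<int> idx((size_t)n);
  for (int j = 0; j < n; ++j) idx[j] = j;
  uint64_t state = (uint64_t)rng_seed * 2862933555777941757ULL + 3037000493ULL;
  int epoch = 0;
  bool converged = false;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle from the private LCG
    for (int j = n - 1; j > 0; --j) {
      state = state * 6364136223846793005ULL + 1442695040888963407ULL;
      int r = (int)((state >> 33) % (uint64_t)(j + 1));
      std::swap(idx[j], idx[r]);
    }
    double pg_max = -1e300, pg_min = 1e300;
    for (int jj = 0; jj < n; ++jj) {
      int j = idx[jj];
      double G = y[j] * (col_dot_w(xi, xv, xp[j], xp[j + 1], w.data()) + b) - 1.0;
      double Cj = cost[j];
      double PG = G;
      if (alpha[j] <= 0.0) PG = G < 0.0 ? G : 0.0;
      else if (alpha[j] >= Cj) PG = G > 0.0 ? G : 0.0;
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[j];
        double a_new = a_old - G / qii[j];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > Cj) a_new = Cj;
        double d = (a_new - a_old) * y[j];
        if (d != 0.0) {
          for (int k = xp[j]; k < xp[j + 1]; ++k) w[xi[k]] += d * xv[k];
          b += d;
          alpha[j] = a_new;
        }
      }
    }
    if (pg_max - pg_min < tol) { converged = true; ++epoch; break; }
  }
  return List::create(_["w"] = wrap(w), _["b"] = b,
                      _["epochs"] = epoch, _["converged"] = converged);
}
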