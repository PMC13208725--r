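// Fast logistic-regression primitives for the MB-MDR engine and the
// permutation machinery. All fits are small (p <= 8) Newton-Raphson
// solves hand-rolled over column pointers with stack storage: an
// order-2 scan at B = 1000 needs ~10^5 fits, so per-fit overhead
// dominates everything else.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

#define MAXP 8

// Cholesky solve of A x = b for p x p SPD A (row-major); A and b are
// overwritten. Returns false if not positive definite.
static bool chol_solve(double* A, double* b, int p, double* diag_inv) {
  // in-place Cholesky A = L L^T
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= A[i * p + k] * A[j * p + k];
      if (i == j) {
        if (s <= 1e-12) return false;
        A[i * p + i] = std::sqrt(s);
      } else {
        A[i * p + j] = s / A[j * p + j];
      }
    }
  }
  // forward then backward substitution
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[i * p + k] * b[k];
    b[i] = s / A[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < p; ++k) s -= A[k * p + i] * b[k];
    b[i] = s / A[i * p + i];
  }
  // diagonal of A^{-1} via columns of identity, if requested
  if (diag_inv) {
    double e[MAXP];
    for (int c = 0; c < p; ++c) {
      std::memset(e, 0, sizeof(double) * p);
      e[c] = 1.0;
      for (int i = 0; i < p; ++i) {
        double s = e[i];
        for (int k = 0; k < i; ++k) s -= A[i * p + k] * e[k];
        e[i] = s / A[i * p + i];
      }
      for (int i = p - 1; i >= 0; --i) {
        double s = e[i];
        for (int k = i + 1; k < p; ++k) s -= A[k * p + i] * e[k];
        e[i] = s / A[i * p + i];
      }
      diag_inv[c] = e[c];
    }
  }
  return true;
}

// Newton-Raphson logistic fit on column pointers. cols[0..p-1] each
// point to n doubles. Returns true on convergence; separation is
// flagged by divergence or a failed Hessian factorization.
static bool logistic_fit(const double* const* cols, int p, int n,
                         const double* y, double* beta, double* se,
                         int max_iter = 30, double tol = 1e-8) {
  std::memset(beta, 0, sizeof(double) * p);
  double grad[MAXP], H[MAXP * MAXP], Hc[MAXP * MAXP], step[MAXP];
  double dinv[MAXP];
  for (int it = 0; it < max_iter; ++it) {
    std::memset(grad, 0, sizeof(double) * p);
    std::memset(H, 0, sizeof(double) * p * p);
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += beta[j] * cols[j][i];
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double r = y[i] - mu;
      for (int j = 0; j < p; ++j) {
        double xj = cols[j][i];
        grad[j] += xj * r;
        double wxj = w * xj;
        for (int k = 0; k <= j; ++k) H[j * p + k] += wxj * cols[k][i];
      }
    }
    for (int j = 0; j < p; ++j)
      for (int k = j + 1; k < p; ++k) H[j * p + k] = H[k * p + j];
    std::memcpy(Hc, H, sizeof(double) * p * p);
    std::memcpy(step, grad, sizeof(double) * p);
    bool last = true;
    if (!chol_solve(Hc, step, p, NULL)) return false;
    double maxstep = 0.0, maxbeta = 0.0;
    for (int j = 0; j < p; ++j) {
      beta[j] += step[j];
      maxstep = std::max(maxstep, std::fabs(step[j]));
      maxbeta = std::max(maxbeta, std::fabs(beta[j]));
    }
    if (maxbeta > 30.0) return false;
    if (maxstep < tol) {
      std::memcpy(Hc, H, sizeof(double) * p * p);
      double dummy[MAXP];
      std::memset(dummy, 0, sizeof(double) * p);
      if (!chol_solve(Hc, dummy, p, dinv)) return false;
      for (int j = 0; j < p; ++j) se[j] = std::sqrt(dinv[j]);
      return last;
    }
  }
  return false;
}

struct MbmdrData {
  const int* cells;     // 1-based cell index per individual
  int K, n, ncov;
  const double* covar;  // column-major n x ncov
};

// One MB-MDR evaluation on a fixed cell partition: per-cell H/L/O
// classification (logistic y ~ 1{cell} + covariates at risk_threshold,
// cells under min_cell are O) followed by pooled H and L Wald tests.
// out: betaH, WH, betaL, WL, NH, NL.
static void mbmdr_eval(const MbmdrData& d, const double* y,
                       double risk_threshold, int min_cell,
                       double* out, int* labels,
                       double* ind /* scratch, length n */,
                       double* ones /* length n of 1s */) {
  const int p = 2 + d.ncov;
  const double* cols[MAXP];
  cols[0] = ones;
  cols[1] = ind;
  for (int j = 0; j < d.ncov; ++j) cols[2 + j] = d.covar + (size_t)j * d.n;
  double beta[MAXP], se[MAXP];

  std::vector<int> cell_n(d.K, 0);
  for (int i = 0; i < d.n; ++i) cell_n[d.cells[i] - 1]++;
  for (int k = 0; k < d.K; ++k) labels[k] = 0;

  for (int k = 0; k < d.K; ++k) {
    if (cell_n[k] < min_cell || cell_n[k] == d.n) continue;
    for (int i = 0; i < d.n; ++i) ind[i] = (d.cells[i] == k + 1) ? 1.0 : 0.0;
    if (!logistic_fit(cols, p, d.n, y, beta, se)) continue;  // separation -> O
    double z = beta[1] / se[1];
    double pv = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    if (pv < risk_threshold) labels[k] = (beta[1] > 0) ? 1 : -1;
  }

  int NH = 0, NL = 0;
  for (int k = 0; k < d.K; ++k) {
    if (labels[k] == 1) NH++;
    else if (labels[k] == -1) NL++;
  }
  out[0] = NA_REAL; out[1] = 0.0; out[2] = NA_REAL; out[3] = 0.0;
  out[4] = NH; out[5] = NL;
  for (int side = 0; side < 2; ++side) {
    if ((side == 0 ? NH : NL) == 0) continue;
    int want = side == 0 ? 1 : -1;
    int n_in = 0;
    for (int i = 0; i < d.n; ++i) {
      bool in = labels[d.cells[i] - 1] == want;
      ind[i] = in ? 1.0 : 0.0;
      n_in += in;
    }
    if (n_in == d.n) continue;  // pooled indicator constant
    if (logistic_fit(cols, p, d.n, y, beta, se)) {
      double z = beta[1] / se[1];
      out[2 * side] = beta[1];
      out[2 * side + 1] = z * z;
    }
  }
}

// [[Rcpp::export]]
NumericVector mbmdr_fit_cpp(IntegerVector cells, int K, NumericVector y,
                            NumericMatrix covar, double risk_threshold,
                            int min_cell) {
  if (2 + covar.ncol() > MAXP) stop("too many covariates");
  MbmdrData d{cells.begin(), K, (int)y.size(), covar.ncol(), covar.begin()};
  std::vector<double> ind(d.n), ones(d.n, 1.0);
  std::vector<int> labels(K);
  double out[6];
  mbmdr_eval(d, REAL(y), risk_threshold, min_cell, out, labels.data(),
             ind.data(), ones.data());
  NumericVector res(out, out + 6);
  res.names() = CharacterVector::create("beta_H", "W_H", "beta_L", "W_L",
                                        "NH", "NL");
  res.attr("labels") = IntegerVector(labels.begin(), labels.end());
  return res;
}

// Permutation null of Wmax: shuffles the status vector (covariates stay
// paired with the factors) B times using R's RNG, re-running the full
// classify-and-pool evaluation each time. Deterministic given set.seed().
// [[Rcpp::export]]
NumericVector mbmdr_perm_cpp(IntegerVector cells, int K, NumericVector y,
                             NumericMatrix covar, int B,
                             double risk_threshold, int min_cell) {
  if (2 + covar.ncol() > MAXP) stop("too many covariates");
  MbmdrData d{cells.begin(), K, (int)y.size(), covar.ncol(), covar.begin()};
  std::vector<double> ind(d.n), ones(d.n, 1.0), yp(REAL(y), REAL(y) + d.n);
  std::vector<int> labels(K);
  double out[6];
  NumericVector wmax(B);
  for (int b = 0; b < B; ++b) {
    for (int i = d.n - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    mbmdr_eval(d, yp.data(), risk_threshold, min_cell, out, labels.data(),
               ind.data(), ones.data());
    wmax[b] = std::max(out[1], out[3]);
  }
  return wmax;
}

static void matrix_cols(NumericMatrix& X, const double** cols) {
  for (int j = 0; j < X.ncol(); ++j) cols[j] = X.begin() + (size_t)j * X.nrow();
}

// General small logistic fit used by permutation wrappers and the
// Monte-Carlo power oracle. Returns beta, se, converged flag.
// [[Rcpp::export]]
List logistic_fit_cpp(NumericMatrix X, NumericVector y) {
  int p = X.ncol(), n = X.nrow();
  if (p > MAXP) stop("at most %d columns supported", MAXP);
  const double* cols[MAXP];
  matrix_cols(X, cols);
  double beta[MAXP], se[MAXP];
  if (!logistic_fit(cols, p, n, REAL(y), beta, se))
    return List::create(_["converged"] = false,
                        _["beta"] = NumericVector(p, NA_REAL),
                        _["se"] = NumericVector(p, NA_REAL));
  return List::create(_["converged"] = true,
                      _["beta"] = NumericVector(beta, beta + p),
                      _["se"] = NumericVector(se, se + p));
}

// Permutation helper for a Wald statistic: permutes y, refits, returns
// |z| for the coefficient at 0-based column `col`, per permutation.
// [[Rcpp::export]]
NumericVector perm_wald_cpp(NumericMatrix X, NumericVector y, int col, int B) {
  int p = X.ncol(), n = X.nrow();
  if (p > MAXP) stop("at most %d columns supported", MAXP);
  const double* cols[MAXP];
  matrix_cols(X, cols);
  std::vector<double> yp(REAL(y), REAL(y) + n);
  double beta[MAXP], se[MAXP];
  NumericVector stat(B);
  for (int b = 0; b < B; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    if (logistic_fit(cols, p, n, yp.data(), beta, se))
      stat[b] = std::fabs(beta[col] / se[col]);
    else
      stat[b] = NA_REAL;
  }
  return stat;
}
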