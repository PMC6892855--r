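#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pathwise solver for L1-penalised logistic regression, used nodewise for
// Ising network estimation.  Objective (per observation, intercept
// unpenalised):
//   (1/n) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ] + lambda * sum_j |beta_j|
// Solved by iteratively reweighted least squares with cyclic coordinate
// descent on the quadratic approximation, warm starts along the lambda path,
// and active-set cycling.  Binary predictor columns are walked through
// precomputed index lists of their nonzero rows, which makes the coordinate
// updates O(#ones) rather than O(n).

// soft threshold; the relative slack keeps a coefficient at exactly zero on
// the knife edge |z| == g (the first path point sits exactly at lambda_max)
static inline double soft(double z, double g) {
  const double gs = g * (1.0 + 1e-7);
  if (z > gs) return z - g;
  if (z < -gs) return z + g;
  return 0.0;
}

// Fit the path.  Beta is p x L, b0 / loglik / df length L.  Writes the number
// of lambda values actually fitted to *L_used: following standard pathwise
// practice, the path stops early once the fractional deviance-explained gain
// per step falls below 1e-5 (or deviance explained exceeds 0.999), so
// near-saturated tail models never enter the candidate set.  Returns the
// 0-based index of the first lambda that failed to converge, or -1.
//
// Each IRLS outer iteration forms the weighted quadratic approximation once
// -- Gram matrix G = X'WX, moments c = X'(W eta + r), h = X'w -- after which
// every coordinate-descent sweep costs O(p^2) independent of n ("covariance
// updates").  Binary predictor columns are walked through precomputed index
// lists of their nonzero rows, so forming the Gram matrix is O(sum #ones * p).
static int lasso_path_core(const double* ydat, const double* Xdat, int n,
                           int p, const double* lambdas, int L, double tol,
                           int max_iter, double* Beta, double* b0v,
                           double* loglik, int* df, int* L_used) {
  std::vector<std::vector<int>> ones(p);
  std::vector<bool> is_binary(p, true);
  for (int j = 0; j < p; ++j) {
    const double* xj = Xdat + (size_t) j * n;
    for (int i = 0; i < n; ++i) {
      if (xj[i] == 1.0) ones[j].push_back(i);
      else if (xj[i] != 0.0) { is_binary[j] = false; break; }
    }
    if (!is_binary[j]) ones[j].clear();
  }
  std::vector<double> eta(n), w(n), r(n), beta(p, 0.0), beta_snap(p);
  std::vector<double> G((size_t) p * p), cvec(p), hvec(p);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += ydat[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));
  for (int i = 0; i < n; ++i) eta[i] = b0;
  const double ll_null = n * (ybar * std::log(ybar) +
                              (1.0 - ybar) * std::log(1.0 - ybar));
  double devratio_prev = 0.0;
  *L_used = L;

  double ll_entry = 0.0;
  for (int l = 0; l < L; ++l) {
    const double lam_n = lambdas[l] * n;  // penalty on the sum scale
    bool converged = false;
    for (int it = 0; it < max_iter; ++it) {
      // quadratic approximation at current eta; the log-likelihood at the
      // entry eta comes for free from the same stable exp/log1p pair, and at
      // convergence (coefficient changes below tol) it is the fitted value
      double Sw = 0.0, Swz = 0.0;
      ll_entry = 0.0;
      for (int i = 0; i < n; ++i) {
        const double e = eta[i];
        double pr, l1pe;  // P(y=1|eta) and log(1 + exp(eta))
        if (e >= 0.0) {
          double t = std::exp(-e);
          pr = 1.0 / (1.0 + t);
          l1pe = e + std::log1p(t);
        } else {
          double t = std::exp(e);
          pr = t / (1.0 + t);
          l1pe = std::log1p(t);
        }
        double wi = pr * (1.0 - pr);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        r[i] = ydat[i] - pr;
        Sw += wi;
        Swz += wi * e + r[i];  // w_i z_i with z = eta + r/w
        ll_entry += ydat[i] * e - l1pe;
      }
      for (int j = 0; j < p; ++j) {
        double hj = 0.0, cj = 0.0;
        if (is_binary[j]) {
          for (int i : ones[j]) { hj += w[i]; cj += w[i] * eta[i] + r[i]; }
          for (int k = j; k < p; ++k) {
            double g;
            if (k == j) {
              g = hj;  // binary column: sum w * x^2 = sum w over its ones
            } else {
              g = 0.0;
              const double* xk = Xdat + (size_t) k * n;
              for (int i : ones[j]) g += w[i] * xk[i];
            }
            G[(size_t) j * p + k] = G[(size_t) k * p + j] = g;
          }
        } else {
          const double* xj = Xdat + (size_t) j * n;
          for (int i = 0; i < n; ++i) {
            hj += w[i] * xj[i];
            cj += xj[i] * (w[i] * eta[i] + r[i]);
          }
          for (int k = j; k < p; ++k) {
            const double* xk = Xdat + (size_t) k * n;
            double g = 0.0;
            for (int i = 0; i < n; ++i) g += w[i] * xj[i] * xk[i];
            G[(size_t) j * p + k] = G[(size_t) k * p + j] = g;
          }
        }
        hvec[j] = hj;
        cvec[j] = cj;
      }
      beta_snap = beta;
      const double b0_snap = b0;
      // coordinate descent on the fixed quadratic, O(p^2) per sweep
      for (int sweep = 0; sweep < 10000; ++sweep) {
        double hb = 0.0;
        for (int j = 0; j < p; ++j) hb += hvec[j] * beta[j];
        double b0_new = (Swz - hb) / Sw;
        double delta = std::fabs(b0_new - b0);
        b0 = b0_new;
        for (int j = 0; j < p; ++j) {
          double gb = 0.0;
          const double* Gj = G.data() + (size_t) j * p;
          for (int k = 0; k < p; ++k) gb += Gj[k] * beta[k];
          gb -= Gj[j] * beta[j];
          double num = cvec[j] - b0 * hvec[j] - gb;
          double bj_new = (Gj[j] > 0.0) ? soft(num, lam_n) / Gj[j] : 0.0;
          delta = std::max(delta, std::fabs(bj_new - beta[j]));
          beta[j] = bj_new;
        }
        if (delta < tol) break;
      }
      // refresh the linear predictor for the next approximation
      for (int i = 0; i < n; ++i) eta[i] = b0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] == 0.0) continue;
        if (is_binary[j]) {
          for (int i : ones[j]) eta[i] += beta[j];
        } else {
          const double* xj = Xdat + (size_t) j * n;
          for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
        }
      }
      double outer_change = std::fabs(b0 - b0_snap);
      for (int j = 0; j < p; ++j)
        outer_change = std::max(outer_change,
                                std::fabs(beta[j] - beta_snap[j]));
      if (outer_change < tol) { converged = true; break; }
    }
    if (!converged) return l;
    const double ll = ll_entry;
    int k = 0;
    for (int j = 0; j < p; ++j) {
      Beta[(size_t) l * p + j] = beta[j];
      if (beta[j] != 0.0) ++k;
    }
    b0v[l] = b0;
    loglik[l] = ll;
    df[l] = k;
    double devratio = 1.0 - ll / ll_null;
    if (l > 0 && (devratio - devratio_prev < 1e-5 * devratio ||
                  devratio > 0.999)) {
      *L_used = l + 1;
      break;
    }
    devratio_prev = devratio;
  }
  return -1;
}

// [[Rcpp::export]]
List lasso_path_cpp(NumericVector y, NumericMatrix X, NumericVector lambdas,
                    double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix Beta(p, L);
  NumericVector b0(L), loglik(L);
  IntegerVector df(L);
  int L_used = L;
  int bad = lasso_path_core(REAL(y), REAL(X), n, p, REAL(lambdas), L, tol,
                            max_iter, REAL(Beta), REAL(b0), REAL(loglik),
                            INTEGER(df), &L_used);
  if (bad >= 0)
    stop("coordinate descent failed to converge at lambda index %d", bad + 1);
  return List::create(_["beta"] = Beta, _["intercepts"] = b0,
                      _["loglik"] = loglik, _["df"] = df,
                      _["n_used"] = L_used);
}

// Nodewise eLasso fit: for each node j, an L1 logistic regression of column j
// on all other columns, lambda selected by EBIC with P = p - 1 candidate
// predictors.  Returns the matrix of directed coefficients B where B(i, j) is
// the coefficient of node i in node j's regression, plus intercepts.
// Symmetrisation (AND/OR rule) is done by the caller.
// [[Rcpp::export]]
List elasso_nodewise_cpp(NumericMatrix Xb, double gamma, int n_lambda,
                         double lambda_ratio, double tol, int max_iter) {
  const int n = Xb.nrow(), p = Xb.ncol();
  NumericMatrix B(p, p);
  NumericVector intercepts(p);
  IntegerVector sel_idx(p);
  std::vector<double> Xo((size_t) n * (p - 1)), yv(n), lambdas(n_lambda);
  std::vector<double> Beta((size_t) (p - 1) * n_lambda), b0(n_lambda),
      loglik(n_lambda);
  std::vector<int> df(n_lambda);

  for (int j = 0; j < p; ++j) {
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) { yv[i] = Xb(i, j); ybar += yv[i]; }
    ybar /= n;
    int c = 0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      for (int i = 0; i < n; ++i) Xo[(size_t) c * n + i] = Xb(i, k);
      ++c;
    }
    // data-derived lambda_max: max |x_k'(y - ybar)| / n over candidates
    double lmax = 0.0;
    for (int k = 0; k < p - 1; ++k) {
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += Xo[(size_t) k * n + i] * (yv[i] - ybar);
      g = std::fabs(g) / n;
      if (g > lmax) lmax = g;
    }
    if (lmax <= 0.0) lmax = 1e-4;
    const double llo = std::log(lmax * lambda_ratio), lhi = std::log(lmax);
    for (int l = 0; l < n_lambda; ++l)
      lambdas[l] = std::exp(lhi + (llo - lhi) * l / (n_lambda - 1.0));

    int L_used = n_lambda;
    int bad = lasso_path_core(yv.data(), Xo.data(), n, p - 1, lambdas.data(),
                              n_lambda, tol, max_iter, Beta.data(), b0.data(),
                              loglik.data(), df.data(), &L_used);
    if (bad >= 0)
      stop("node %d: coordinate descent failed to converge at lambda index %d",
           j + 1, bad + 1);
    // EBIC selection; ties go to the larger lambda (sparser-first ordering).
    const double logn = std::log((double) n), logP = std::log((double) p - 1);
    double best = R_PosInf;
    int best_l = 0;
    for (int l = 0; l < L_used; ++l) {
      double e = -2.0 * loglik[l] + df[l] * logn + 2.0 * gamma * df[l] * logP;
      if (e < best - 1e-12) { best = e; best_l = l; }
    }
    c = 0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      B(k, j) = Beta[(size_t) best_l * (p - 1) + c];
      ++c;
    }
    intercepts[j] = b0[best_l];
    sel_idx[j] = best_l + 1;
  }
  return List::create(_["directed"] = B, _["intercepts"] = intercepts,
                      _["lambda_index"] = sel_idx);
}

// Single-site Gibbs sampler for an Ising model in {0,1} coding:
//   P(x_i = 1 | rest) = logistic(tau_i + sum_j beta_ij x_j)
// Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericVector tau, NumericMatrix beta, int n,
                               int burn_in, int thinning) {
  const int p = tau.size();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int j = 0; j < p; ++j) x[j] = (unif_rand() < 0.5) ? 1 : 0;
  const int total = burn_in + n * thinning;
  int kept = 0;
  for (int t = 0; t < total; ++t) {
    for (int j = 0; j < p; ++j) {
      double eta = tau[j];
      for (int k = 0; k < p; ++k)
        if (x[k]) eta += beta(j, k);
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
    if (t >= burn_in && (t - burn_in) % thinning == 0 && kept < n) {
      for (int j = 0; j < p; ++j) out(kept, j) = x[j];
      ++kept;
    }
  }
  return out;
}
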