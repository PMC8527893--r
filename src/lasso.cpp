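#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// L1-penalised logistic regression by iteratively reweighted least squares
// with an inner cyclic coordinate descent (active-set strategy), warm-started
// along a descending lambda sequence.  Objective (natural log, unpenalised
// intercept):
//   J(w,b) = -(1/n) sum_i [ y_i log p_i + (1-y_i) log(1-p_i) ] + lambda ||w||_1
// Features are assumed standardised by the caller.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double objective(const double* X, const double* y, int n, int p,
                        const double* w, double b, double lambda,
                        double* eta_out) {
  double nll = 0.0, pen = 0.0;
  for (int i = 0; i < n; ++i) eta_out[i] = b;
  for (int j = 0; j < p; ++j) {
    double wj = w[j];
    if (wj == 0.0) continue;
    pen += std::fabs(wj);
    const double* xj = X + (size_t)j * n;
    for (int i = 0; i < n; ++i) eta_out[i] += xj[i] * wj;
  }
  for (int i = 0; i < n; ++i) {
    double e = eta_out[i];
    double l = (e > 0.0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    nll += l - y[i] * e;
  }
  return nll / n + lambda * pen;
}

// Max violation of the stationarity conditions at (w, b), eta given.
static double kkt_violation(const double* X, const double* y, int n, int p,
                            const double* w, double lambda,
                            const double* eta) {
  std::vector<double> resid(n);
  double gi = 0.0;
  for (int i = 0; i < n; ++i) {
    double pr = 1.0 / (1.0 + std::exp(-eta[i]));
    resid[i] = y[i] - pr;
    gi += resid[i];
  }
  double viol = std::fabs(gi / n);
  for (int j = 0; j < p; ++j) {
    const double* xj = X + (size_t)j * n;
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * resid[i];
    g /= n;
    double v = (w[j] != 0.0) ? std::fabs(g - lambda * ((w[j] > 0) - (w[j] < 0)))
                             : std::max(0.0, std::fabs(g) - lambda);
    if (v > viol) viol = v;
  }
  return viol;
}

// one cycle of coordinate updates over the given index set; returns max delta
static double cd_cycle(const double* X, int n, const double* v, double vsum,
                       double* r, double* w, double& b, double lambda,
                       const std::vector<int>& idx) {
  double max_delta = 0.0;
  // unpenalised intercept
  {
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += v[i] * r[i];
    double db = num / vsum;
    if (db != 0.0) {
      b += db;
      for (int i = 0; i < n; ++i) r[i] -= db;
      double ad = std::fabs(db);
      if (ad > max_delta) max_delta = ad;
    }
  }
  for (int j : idx) {
    const double* xj = X + (size_t)j * n;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      double vx = v[i] * xj[i];
      num += vx * r[i];
      den += vx * xj[i];
    }
    den /= n;
    if (den < 1e-12) continue;
    double wj_new = soft_threshold(num / n + den * w[j], lambda) / den;
    if (std::fabs(wj_new) < 1e-10) wj_new = 0.0;  // roundoff at the KKT boundary
    double d = wj_new - w[j];
    if (d != 0.0) {
      w[j] = wj_new;
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      double ad = std::fabs(d);
      if (ad > max_delta) max_delta = ad;
    }
  }
  return max_delta;
}

// IRLS + coordinate descent restricted to a candidate feature set.
// Returns true when the objective converged and the KKT conditions hold on
// the candidate set.  eta is kept current on exit.
static bool irls_on_set(const double* X, const double* y, int n, int p,
                        double lambda, double* w, double& b, double tol,
                        int max_outer, std::vector<double>* obj_trace,
                        const std::vector<int>& cand, std::vector<double>& eta) {
  std::vector<double> v(n), r(n), w_prev(p);
  std::vector<int> active;

  double obj_old = objective(X, y, n, p, w, b, lambda, eta.data());
  if (obj_trace) obj_trace->push_back(obj_old);
  bool converged = false;
  double cd_tol = tol * 1e-2;
  if (cd_tol < 1e-8) cd_tol = 1e-8;
  if (cd_tol > 1e-6) cd_tol = 1e-6;

  for (int outer = 0; outer < max_outer; ++outer) {
    // quadratic approximation at current (w, b); eta is current
    double vsum = 0.0;
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-eta[i]));
      if (pr < 1e-5) pr = 1e-5;
      if (pr > 1.0 - 1e-5) pr = 1.0 - 1e-5;
      double vi = pr * (1.0 - pr);
      v[i] = vi;
      vsum += vi;
      r[i] = (y[i] - pr) / vi;  // z - eta
    }
    std::copy(w, w + p, w_prev.begin());
    double b_prev = b;

    // inner CD: candidate cycle, then iterate the active set, then verify
    cd_cycle(X, n, v.data(), vsum, r.data(), w, b, lambda, cand);
    for (int round = 0; round < 10; ++round) {
      active.clear();
      for (int j : cand)
        if (w[j] != 0.0) active.push_back(j);
      double md;
      int sweeps = 0;
      do {
        md = cd_cycle(X, n, v.data(), vsum, r.data(), w, b, lambda, active);
      } while (md > cd_tol && ++sweeps < 25);
      md = cd_cycle(X, n, v.data(), vsum, r.data(), w, b, lambda, cand);
      if (md <= cd_tol) break;
    }

    // safeguard: the IRLS step must not increase the true objective
    double obj_new = objective(X, y, n, p, w, b, lambda, eta.data());
    int halvings = 0;
    while (obj_new > obj_old + 1e-12 && halvings < 20) {
      for (int j = 0; j < p; ++j) w[j] = 0.5 * (w[j] + w_prev[j]);
      b = 0.5 * (b + b_prev);
      obj_new = objective(X, y, n, p, w, b, lambda, eta.data());
      ++halvings;
    }
    if (halvings == 20) {
      std::copy(w_prev.begin(), w_prev.end(), w);
      b = b_prev;
      obj_new = objective(X, y, n, p, w, b, lambda, eta.data());
    }
    if (obj_trace) obj_trace->push_back(obj_new);

    if (std::fabs(obj_old - obj_new) < tol) {
      // KKT on the candidate set only; the caller verifies the full set
      bool ok = true;
      std::vector<double> resid(n);
      double gi = 0.0;
      for (int i = 0; i < n; ++i) {
        double pr = 1.0 / (1.0 + std::exp(-eta[i]));
        resid[i] = y[i] - pr;
        gi += resid[i];
      }
      if (std::fabs(gi / n) > 1e-6) ok = false;
      for (size_t ci = 0; ok && ci < cand.size(); ++ci) {
        int j = cand[ci];
        const double* xj = X + (size_t)j * n;
        double g = 0.0;
        for (int i = 0; i < n; ++i) g += xj[i] * resid[i];
        g /= n;
        double viol = (w[j] != 0.0)
          ? std::fabs(g - lambda * ((w[j] > 0) - (w[j] < 0)))
          : std::max(0.0, std::fabs(g) - lambda);
        if (viol > 1e-6) ok = false;
      }
      if (ok) { converged = true; break; }
    }
    obj_old = obj_new;
  }
  return converged;
}

// One fit at a single lambda, warm-started from (w, b) in place, with
// sequential strong-rule screening: only features whose score gradient at
// the warm start exceeds 2*lambda - lambda_prev enter the working set, and
// the full KKT conditions are verified (violators added, refit) on exit.
static bool fit_single(const double* X, const double* y, int n, int p,
                       double lambda, double* w, double& b, double tol,
                       int max_outer, std::vector<double>* obj_trace,
                       double lambda_prev = -1.0) {
  std::vector<double> eta(n, 0.0);
  std::vector<int> cand;
  cand.reserve(p);

  if (lambda_prev > lambda) {
    // gradient at the warm start
    {
      double e;
      for (int i = 0; i < n; ++i) {
        e = b;
        eta[i] = e;
      }
      for (int j = 0; j < p; ++j) {
        if (w[j] == 0.0) continue;
        const double* xj = X + (size_t)j * n;
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * w[j];
      }
    }
    std::vector<double> resid(n);
    for (int i = 0; i < n; ++i)
      resid[i] = y[i] - 1.0 / (1.0 + std::exp(-eta[i]));
    double thr = 2.0 * lambda - lambda_prev;
    for (int j = 0; j < p; ++j) {
      if (w[j] != 0.0) { cand.push_back(j); continue; }
      const double* xj = X + (size_t)j * n;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += xj[i] * resid[i];
      if (std::fabs(g) / n > thr) cand.push_back(j);
    }
  } else {
    for (int j = 0; j < p; ++j) cand.push_back(j);
  }

  bool converged = false;
  for (int round = 0; round < 5; ++round) {
    converged = irls_on_set(X, y, n, p, lambda, w, b, tol, max_outer,
                            obj_trace, cand, eta);
    if ((int)cand.size() == p) break;
    // full-set KKT check; admit violators and refit
    std::vector<double> resid(n);
    for (int i = 0; i < n; ++i)
      resid[i] = y[i] - 1.0 / (1.0 + std::exp(-eta[i]));
    std::vector<bool> in_cand(p, false);
    for (int j : cand) in_cand[j] = true;
    bool any = false;
    for (int j = 0; j < p; ++j) {
      if (in_cand[j]) continue;
      const double* xj = X + (size_t)j * n;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += xj[i] * resid[i];
      if (std::fabs(g) / n > lambda + 1e-7) {
        cand.push_back(j);
        any = true;
      }
    }
    if (!any) break;
  }
  return converged;
}

static std::vector<int> descending_order(const NumericVector& lambda) {
  std::vector<int> ord(lambda.size());
  for (int l = 0; l < (int)ord.size(); ++l) ord[l] = l;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return lambda[a] > lambda[b]; });
  return ord;
}

// [[Rcpp::export]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                   double tol = 1e-9, int max_outer = 100,
                   bool trace_objective = false) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix W(p, L);
  NumericVector intercepts(L);
  LogicalVector conv(L);
  IntegerVector nnz(L);
  List traces(L);

  std::vector<int> ord = descending_order(lambda);
  std::vector<double> w(p, 0.0);
  double ybar = mean(y);
  if (ybar <= 0.0 || ybar >= 1.0) stop("labels must contain both classes");
  double b = std::log(ybar / (1.0 - ybar));

  for (int k = 0; k < L; ++k) {
    int l = ord[k];
    std::vector<double> tr;
    double lprev = (k == 0) ? -1.0 : lambda[ord[k - 1]];
    conv[l] = fit_single(X.begin(), y.begin(), n, p, lambda[l], w.data(), b,
                         tol, max_outer, trace_objective ? &tr : nullptr,
                         lprev);
    if (trace_objective) traces[l] = wrap(tr);
    intercepts[l] = b;
    int m = 0;
    for (int j = 0; j < p; ++j) {
      W(j, l) = w[j];
      if (w[j] != 0.0) ++m;
    }
    nnz[l] = m;
  }
  List out = List::create(_["weights"] = W, _["intercept"] = intercepts,
                          _["lambda"] = lambda, _["n_nonzero"] = nnz,
                          _["converged"] = conv);
  if (trace_objective) out["objective_trace"] = traces;
  return out;
}

// [[Rcpp::export]]
double kkt_max_violation(NumericMatrix X, NumericVector y, NumericVector w,
                         double b, double lambda) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n, b);
  for (int j = 0; j < p; ++j) {
    if (w[j] == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * w[j];
  }
  return kkt_violation(X.begin(), y.begin(), n, p, REAL(w), lambda,
                       eta.data());
}

// Per-fold held-out mean binomial deviance along a lambda path.
// fold_id is 1-based; each fold's path is fit on the remaining rows.
// [[Rcpp::export]]
NumericMatrix cv_deviance_path(NumericMatrix X, NumericVector y,
                               NumericVector lambda, IntegerVector fold_id,
                               int k_folds, double tol = 1e-8,
                               int max_outer = 50) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix dev(k_folds, L);
  std::vector<int> ord = descending_order(lambda);

  for (int f = 1; f <= k_folds; ++f) {
    std::vector<int> tr_idx, te_idx;
    for (int i = 0; i < n; ++i)
      (fold_id[i] == f ? te_idx : tr_idx).push_back(i);
    if (te_idx.empty() || tr_idx.empty())
      stop("fold %d leaves an empty train or test set", f);
    const int ntr = (int)tr_idx.size();

    std::vector<double> Xtr((size_t)ntr * p), ytr(ntr);
    for (int i = 0; i < ntr; ++i) ytr[i] = y[tr_idx[i]];
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double* tj = Xtr.data() + (size_t)j * ntr;
      for (int i = 0; i < ntr; ++i) tj[i] = xj[tr_idx[i]];
    }
    double ybar = 0.0;
    for (int i = 0; i < ntr; ++i) ybar += ytr[i];
    ybar /= ntr;
    if (ybar <= 0.0 || ybar >= 1.0)
      stop("fold %d training data has a single class", f);

    std::vector<double> w(p, 0.0);
    double b = std::log(ybar / (1.0 - ybar));
    for (int k = 0; k < L; ++k) {
      int l = ord[k];
      double lprev = (k == 0) ? -1.0 : lambda[ord[k - 1]];
      fit_single(Xtr.data(), ytr.data(), ntr, p, lambda[l], w.data(), b, tol,
                 max_outer, nullptr, lprev);
      double d = 0.0;
      for (size_t i = 0; i < te_idx.size(); ++i) {
        double eta = b;
        for (int j = 0; j < p; ++j)
          if (w[j] != 0.0) eta += X(te_idx[i], j) * w[j];
        double l1 = (eta > 0.0) ? eta + std::log1p(std::exp(-eta))
                                : std::log1p(std::exp(eta));
        d += 2.0 * (l1 - y[te_idx[i]] * eta);
      }
      dev(f - 1, l) = d / te_idx.size();
    }
  }
  return dev;
}
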