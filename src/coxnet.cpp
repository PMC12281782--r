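// Elastic-net penalized Cox (Breslow ties) core: iteratively reweighted
// least squares with cyclic coordinate descent. Called with data sorted by
// increasing time and columns already standardized; the R wrapper owns
// validation, standardization and back-scaling.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Derivs {
  double loglik;
  std::vector<double> g, h;
};

// Breslow partial log-likelihood and per-subject gradient/diagonal Hessian
// wrt eta. Data sorted ascending by time. eta is shifted by its maximum for
// overflow safety; the shift cancels exactly in the log-likelihood.
Derivs cox_derivs(const std::vector<double>& eta, const NumericVector& time,
                  const IntegerVector& event) {
  int n = eta.size();
  Derivs d;
  d.g.assign(n, 0.0);
  d.h.assign(n, 0.0);
  double shift = *std::max_element(eta.begin(), eta.end());
  std::vector<double> theta(n);
  for (int i = 0; i < n; ++i) theta[i] = std::exp(eta[i] - shift);
  // suffix sums of theta give S0 at each entry's time
  std::vector<double> suffix(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) suffix[i] = suffix[i + 1] + theta[i];
  double ll = 0.0, ca = 0.0, cb = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    int dcount = 0;
    double esum = 0.0;
    while (j < n && time[j] == time[i]) {
      if (event[j]) { ++dcount; esum += eta[j]; }
      ++j;
    }
    if (dcount > 0) {
      double s0 = suffix[i];            // risk set: all with t >= time[i]
      ll += esum - dcount * (std::log(s0) + shift);
      ca += dcount / s0;
      cb += dcount / (s0 * s0);
    }
    // every subject in this tie group shares A = ca, B = cb so far
    for (int k = i; k < j; ++k) {
      double g = (event[k] ? 1.0 : 0.0) - theta[k] * ca;
      double h = theta[k] * ca - theta[k] * theta[k] * cb;
      d.g[k] = g;
      d.h[k] = h > 0 ? h : 0.0;
    }
    i = j;
  }
  d.loglik = ll;
  return d;
}

inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

} // namespace

// [[Rcpp::export(name = ".cox_cd_core")]]
List cox_cd_core(const NumericMatrix& X, const NumericVector& time,
                 const IntegerVector& event, double l1, double lambda,
                 const NumericVector& beta_init, int max_iter, double tol) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eta(n, 0.0);
  for (int k = 0; k < p; ++k)
    if (beta[k] != 0.0)
      for (int i = 0; i < n; ++i) eta[i] += X(i, k) * beta[k];

  auto objective = [&](const std::vector<double>& b, double ll) {
    double pen = 0.0;
    for (int k = 0; k < p; ++k)
      pen += l1 * std::fabs(b[k]) + 0.5 * (1.0 - l1) * b[k] * b[k];
    return -ll / n + lambda * pen;
  };

  Derivs d = cox_derivs(eta, time, event);
  double obj = objective(beta, d.loglik);
  std::vector<double> obj_trace{obj};
  bool converged = false;
  std::vector<double> w(n), z(n), beta_new(p), eta_w(n), eta_try(n), b_try(p);

  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      w[i] = d.h[i] > 1e-9 ? d.h[i] : 1e-9;
      z[i] = eta[i] + d.g[i] / w[i];
    }
    beta_new = beta;
    eta_w = eta;
    // cyclic coordinate descent on the penalized weighted least squares
    for (int sweep = 0; sweep < 100; ++sweep) {
      double maxdel = 0.0;
      for (int k = 0; k < p; ++k) {
        double num = 0.0, den = 0.0;
        for (int i = 0; i < n; ++i) {
          double xik = X(i, k);
          double r = z[i] - eta_w[i] + xik * beta_new[k];
          num += w[i] * xik * r;
          den += w[i] * xik * xik;
        }
        num /= n; den /= n;
        double bk = soft(num, lambda * l1) / (den + lambda * (1.0 - l1));
        double del = bk - beta_new[k];
        if (del != 0.0) {
          for (int i = 0; i < n; ++i) eta_w[i] += X(i, k) * del;
          beta_new[k] = bk;
          double a = std::fabs(del);
          if (a > maxdel) maxdel = a;
        }
      }
      if (maxdel < tol * 10.0) break;
    }
    // step-halving guard: the penalized objective must not increase; if no
    // admissible step improves it we are at numerical convergence
    double step = 1.0;
    double o_try = 0.0;
    bool improved = true;
    Derivs d_try;
    while (true) {
      for (int k = 0; k < p; ++k)
        b_try[k] = beta[k] + step * (beta_new[k] - beta[k]);
      for (int i = 0; i < n; ++i)
        eta_try[i] = eta[i] + step * (eta_w[i] - eta[i]);
      d_try = cox_derivs(eta_try, time, event);
      o_try = objective(b_try, d_try.loglik);
      if (o_try <= obj + 1e-12) break;
      if (step < 1e-4) { improved = false; break; }
      step /= 2.0;
    }
    if (!improved) { converged = true; break; }
    double delta = 0.0;
    for (int k = 0; k < p; ++k) {
      double a = std::fabs(b_try[k] - beta[k]);
      if (a > delta) delta = a;
    }
    double dobj = obj - o_try;
    beta = b_try;
    eta = eta_try;
    d = d_try;
    obj = o_try;
    obj_trace.push_back(obj);
    if (delta < tol || dobj < 1e-13 * (std::fabs(obj) + 1.0)) {
      converged = true;
      break;
    }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["objective"] = NumericVector(obj_trace.begin(),
                                                     obj_trace.end()),
                      _["converged"] = converged);
}
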