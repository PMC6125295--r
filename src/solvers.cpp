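#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// one analytic SMO pair update; returns true if any alpha moved
static bool smo_pair_update(const NumericMatrix &K, const NumericVector &y,
                            double C, std::vector<double> &alpha,
                            std::vector<double> &f, int i, int j,
                            double Ei) {
  int n = K.nrow();
  double Ej = f[j] - y[j];
  double L, H;
  if (y[i] != y[j]) {
    L = std::max(0.0, alpha[j] - alpha[i]);
    H = std::min(C, C + alpha[j] - alpha[i]);
  } else {
    L = std::max(0.0, alpha[i] + alpha[j] - C);
    H = std::min(C, alpha[i] + alpha[j]);
  }
  if (L >= H) return false;
  double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
  double aj_new;
  if (eta > 0.0) {
    aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
  } else {
    // flat direction: move to the feasible end that increases the dual
    double slope = y[j] * (Ei - Ej);
    aj_new = slope > 0 ? H : L;
  }
  // snap alphas sitting at floating-point distance from a bound onto it,
  // so bound-set membership (I_up/I_low) is decided cleanly next round
  double snap = 1e-12 * C;
  if (aj_new < snap) aj_new = 0.0;
  else if (aj_new > C - snap) aj_new = C;
  double ai_new = alpha[i] + y[i] * y[j] * (alpha[j] - aj_new);
  if (ai_new < snap) ai_new = 0.0;
  else if (ai_new > C - snap) ai_new = C;
  double di = ai_new - alpha[i], dj = aj_new - alpha[j];
  if (std::fabs(di) <= snap && std::fabs(dj) <= snap) return false;
  alpha[i] = ai_new; alpha[j] = aj_new;
  for (int t = 0; t < n; ++t)
    f[t] += di * y[i] * K(i, t) + dj * y[j] * K(j, t);
  return true;
}

// Soft-margin SVM dual, maximized in alpha:
//   W(a) = sum_i a_i - 0.5 * sum_ij a_i a_j y_i y_j K_ij,  0 <= a_i <= C
// ISDA: no equality constraint (bias absorbed by a kernel offset already
// added into K). Coordinate ascent over subject indices in ascending order;
// each update is the exact single-coordinate maximizer clipped to [0, C].
// Convergence: max KKT violation <= max(tol, 1e-12 * max|gradient|).
// [[Rcpp::export]]
List isda_solve_cpp(NumericMatrix K, NumericVector y, double C, double tol,
                    double max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  double iter = 0.0;
  bool converged = false;
  double maxviol = 0.0;
  while (iter < max_iter) {
    // one sweep in ascending index order
    for (int i = 0; i < n && iter < max_iter; ++i) {
      double g = 1.0 - y[i] * f[i];        // dW/da_i
      double kii = K(i, i);
      if (kii <= 0.0) continue;            // zero curvature: skip
      double anew = alpha[i] + g / kii;
      if (anew < 0.0) anew = 0.0;
      if (anew > C) anew = C;
      double delta = anew - alpha[i];
      if (delta != 0.0) {
        alpha[i] = anew;
        double dy = delta * y[i];
        for (int j = 0; j < n; ++j) f[j] += dy * K(i, j);
      }
      iter += 1.0;
    }
    // KKT check over all coordinates
    maxviol = 0.0;
    double maxg = 0.0, maxf = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = 1.0 - y[i] * f[i];
      double viol;
      if (alpha[i] <= 0.0) viol = g > 0.0 ? g : 0.0;
      else if (alpha[i] >= C) viol = -g > 0.0 ? -g : 0.0;
      else viol = std::fabs(g);
      if (viol > maxviol) maxviol = viol;
      if (std::fabs(g) > maxg) maxg = std::fabs(g);
      if (std::fabs(f[i]) > maxf) maxf = std::fabs(f[i]);
    }
    // a nominal tolerance of zero becomes a machine-precision floor: the
    // initial gradient is 1, and rounding in the cached f scales with |f|
    double eff = std::max(tol, 1e-12 * std::max(1.0, maxg));
    eff = std::max(eff, 64.0 * DBL_EPSILON * maxf);
    if (maxviol <= eff) { converged = true; break; }
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["kkt_violation"] = maxviol);
}

// SMO: same dual with the equality constraint sum_i a_i y_i = 0 and an
// explicit bias. Working pair: first index = maximal KKT violator on the
// "up" side; second index = the "low"-side point giving the largest
// |E_i - E_j| gain. Stop when m(alpha) - M(alpha) <= tol (Keerthi gap).
// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C, double tol,
                   double max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  double iter = 0.0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;
  while (iter < max_iter) {
    // m = max over I_up of (y_i - f_i); M = min over I_low of (y_i - f_i)
    int i_up = -1, i_low = -1;
    m_up = -HUGE_VAL; m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - f[t];
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > m_up) { m_up = v; i_up = t; }
      if (in_low && v < m_low) { m_low = v; i_low = t; }
    }
    if (i_up < 0 || i_low < 0 || m_up - m_low <= tol) {
      converged = true;
      break;
    }
    int i = i_up;
    double Ei = f[i] - y[i];
    // second choice by maximal second-order gain among violating low-side
    // candidates: gain = (v_i - v_t)^2 / (2 eta_it); provably convergent
    int j = i_low;
    double best = -1.0;
    for (int t = 0; t < n; ++t) {
      if (t == i) continue;
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!in_low) continue;
      double vt = y[t] - f[t];
      double diff = m_up - vt;
      if (diff <= 0.0) continue;      // not a violating partner for i
      double eta = K(i, i) + K(t, t) - 2.0 * K(i, t);
      if (eta <= 0.0) eta = 1e-12;
      double gain = diff * diff / (2.0 * eta);
      if (gain > best) { best = gain; j = t; }
    }
    // analytic two-variable solve; if the gain-chosen partner is blocked
    // (no feasible movement), fall back to the maximal violating pair,
    // which by construction of the up/low sets always makes progress
    bool moved = smo_pair_update(K, y, C, alpha, f, i, j, Ei);
    if (!moved && j != i_low)
      moved = smo_pair_update(K, y, C, alpha, f, i, i_low, Ei);
    iter += 1.0;
    if (!moved) continue;
  }
  // bias: average y_i - f_i over unbounded support vectors, else gap midpoint
  double bsum = 0.0; int bcount = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-8 * C && alpha[t] < C * (1.0 - 1e-8)) {
      bsum += y[t] - f[t];
      ++bcount;
    }
  double b;
  if (bcount > 0) b = bsum / bcount;
  else b = 0.5 * (m_up + m_low);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["bias"] = b,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["kkt_violation"] =
                        (std::isfinite(m_up) && std::isfinite(m_low))
                          ? std::max(0.0, m_up - m_low) : 0.0);
}
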