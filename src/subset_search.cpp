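// Random p-subset searches for high-breakdown regression: the
// concentration (C-step) algorithm for least trimmed squares and the
// subsampling + I-step search for the bisquare S-estimator. Both use a
// private mt19937 stream so results depend only on the seed argument,
// never on R's RNG state.
#include <RcppArmadillo.h>
#include <algorithm>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Draw p distinct row indices uniformly (partial Fisher-Yates).
uvec draw_subset(std::mt19937 &rng, int n, int p) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  uvec out(p);
  for (int j = 0; j < p; ++j) {
    std::uniform_int_distribution<int> unif(j, n - 1);
    int k = unif(rng);
    std::swap(pool[j], pool[k]);
    out[j] = pool[j];
  }
  return out;
}

bool ls_on_rows(const mat &X, const vec &y, const uvec &idx, vec &beta) {
  mat Xs = X.rows(idx);
  vec ys = y(idx);
  return solve(beta, Xs, ys, solve_opts::no_approx);
}

// Indices of the h smallest squared residuals; ties broken by row index
// (nth_element on (r2, index) pairs) so the result is deterministic.
uvec smallest_h(const vec &r2, int h) {
  int n = r2.n_elem;
  std::vector<std::pair<double, int>> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = std::make_pair(r2[i], i);
  std::nth_element(ord.begin(), ord.begin() + h - 1, ord.end());
  uvec out(h);
  for (int i = 0; i < h; ++i) out[i] = ord[i].second;
  return std::sort(out.begin(), out.end()), out;
}

double trimmed_obj(const vec &r2, int h) {
  std::vector<double> v(r2.begin(), r2.end());
  std::nth_element(v.begin(), v.begin() + h - 1, v.end());
  double s = 0.0;
  for (int i = 0; i < h; ++i) s += v[i];
  return s;
}

// One concentration step: refit LS on the h rows with smallest squared
// residuals under the current fit. Returns false if the subset is singular.
bool c_step(const mat &X, const vec &y, int h, vec &beta) {
  vec r2 = square(y - X * beta);
  uvec idx = smallest_h(r2, h);
  vec bnew;
  if (!ls_on_rows(X, y, idx, bnew)) return false;
  beta = bnew;
  return true;
}

// --- bisquare rho/weight for the S-stage, rho(inf) = c^2/6 ---
double rho_bisq(double u, double c) {
  double a = std::abs(u);
  if (a >= c) return c * c / 6.0;
  double t = u / c, t2 = t * t;
  return (u * u / 2.0) * (1.0 - t2 + t2 * t2 / 3.0);
}

double wgt_bisq(double u, double c) {
  double a = std::abs(u);
  if (a >= c) return 0.0;
  double t = 1.0 - (u / c) * (u / c);
  return t * t;
}

// M-scale: solve mean(rho(r/s)) = b by the fixed-point iteration
// s^2 <- s^2 * mean(rho(r/s)) / b, started from the MAD.
double m_scale(const vec &r, double c, double b, double s0) {
  double s = s0;
  if (s <= 0.0) return 0.0;
  for (int it = 0; it < 200; ++it) {
    double m = 0.0;
    for (uword i = 0; i < r.n_elem; ++i) m += rho_bisq(r[i] / s, c);
    m /= r.n_elem;
    double snew = s * std::sqrt(m / b);
    if (std::abs(snew - s) <= 1e-12 * s) return snew;
    s = snew;
  }
  return s;
}

double mad0(const vec &r) {
  vec a = abs(r - median(r));
  return median(a) / 0.6745;
}

} // namespace

// Fast LTS: n_starts random p-subsets, n_csteps concentration steps each,
// then the n_keep best candidates are concentrated to convergence.
// Returns the best coefficients, covered h-subset (1-based), objective and
// the objective trace of the winning candidate's full concentration.
// [[Rcpp::export]]
Rcpp::List cpp_lts(const arma::mat &X, const arma::vec &y, int h,
                   int n_starts, int n_csteps, int n_keep,
                   unsigned int seed) {
  int n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(seed);
  std::vector<std::pair<double, vec>> cand;

  for (int s = 0; s < n_starts; ++s) {
    vec beta;
    bool ok = false;
    for (int tries = 0; tries < 50 && !ok; ++tries)
      ok = ls_on_rows(X, y, draw_subset(rng, n, p), beta);
    if (!ok) continue;
    for (int k = 0; k < n_csteps; ++k)
      if (!c_step(X, y, h, beta)) break;
    cand.push_back(std::make_pair(trimmed_obj(square(y - X * beta), h), beta));
  }
  if (cand.empty()) Rcpp::stop("no non-singular p-subset found");

  std::sort(cand.begin(), cand.end(),
            [](const std::pair<double, vec> &a, const std::pair<double, vec> &b) {
              return a.first < b.first;
            });
  int keep = std::min<int>(n_keep, cand.size());

  double best_obj = datum::inf;
  vec best_beta;
  std::vector<double> best_trace;
  for (int j = 0; j < keep; ++j) {
    vec beta = cand[j].second;
    double obj = cand[j].first;
    std::vector<double> trace;
    trace.push_back(obj);
    for (int k = 0; k < 200; ++k) {
      if (!c_step(X, y, h, beta)) break;
      double onew = trimmed_obj(square(y - X * beta), h);
      trace.push_back(onew);
      if (onew >= obj * (1.0 - 1e-12)) { obj = std::min(obj, onew); break; }
      obj = onew;
    }
    if (obj < best_obj) {
      best_obj = obj;
      best_beta = beta;
      best_trace = trace;
    }
  }

  uvec cover = smallest_h(square(y - X * best_beta), h) + 1;
  return Rcpp::List::create(
      Rcpp::Named("beta") = best_beta,
      Rcpp::Named("objective") = best_obj,
      Rcpp::Named("subset") = cover,
      Rcpp::Named("trace") = best_trace);
}

// S-estimator search: random p-subsets scored by the bisquare M-scale of
// their residuals, k_steps weighted-LS refinement steps per start, best
// n_keep refined to convergence. b is the consistency target
// (breakdown point times c^2/6).
// [[Rcpp::export]]
Rcpp::List cpp_s(const arma::mat &X, const arma::vec &y, double c,
                 double b, int n_starts, int k_steps, int n_keep,
                 unsigned int seed) {
  int n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(seed);

  auto refine = [&](vec &beta, double &s, int steps, bool to_conv) {
    for (int k = 0; k < steps; ++k) {
      vec r = y - X * beta;
      if (s <= 0.0) return;
      vec w(n);
      for (int i = 0; i < n; ++i) w[i] = wgt_bisq(r[i] / s, c);
      if (accu(w) <= 0.0) return;
      vec sw = sqrt(w);
      mat Xw = X.each_col() % sw;
      vec bnew;
      if (!solve(bnew, Xw, y % sw, solve_opts::no_approx)) return;
      double step = norm(bnew - beta, "inf");
      beta = bnew;
      r = y - X * beta;
      double s0 = mad0(r);
      double snew = (s0 <= 0.0) ? 0.0 : m_scale(r, c, b, s);
      if (snew <= 0.0) { s = 0.0; return; }
      s = snew;
      if (to_conv && step <= 1e-9 * (1.0 + norm(beta, "inf"))) return;
    }
  };

  std::vector<std::pair<double, vec>> cand;
  for (int st = 0; st < n_starts; ++st) {
    vec beta;
    bool ok = false;
    for (int tries = 0; tries < 50 && !ok; ++tries)
      ok = ls_on_rows(X, y, draw_subset(rng, n, p), beta);
    if (!ok) continue;
    vec r = y - X * beta;
    double s0 = mad0(r);
    if (s0 <= 0.0) {
      // exact fit of more than half the data: scale 0 is the optimum
      return Rcpp::List::create(Rcpp::Named("beta") = beta,
                                Rcpp::Named("scale") = 0.0);
    }
    double s = m_scale(r, c, b, s0);
    refine(beta, s, k_steps, false);
    if (s <= 0.0)
      return Rcpp::List::create(Rcpp::Named("beta") = beta,
                                Rcpp::Named("scale") = 0.0);
    cand.push_back(std::make_pair(s, beta));
  }
  if (cand.empty()) Rcpp::stop("no non-singular p-subset found");

  std::sort(cand.begin(), cand.end(),
            [](const std::pair<double, vec> &a, const std::pair<double, vec> &b2) {
              return a.first < b2.first;
            });
  int keep = std::min<int>(n_keep, cand.size());
  double best_s = datum::inf;
  vec best_beta;
  for (int j = 0; j < keep; ++j) {
    vec beta = cand[j].second;
    double s = cand[j].first;
    refine(beta, s, 100, true);
    if (s < best_s) { best_s = s; best_beta = beta; }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = best_beta,
                            Rcpp::Named("scale") = best_s);
}
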