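#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Wang-Landau walk over the instantaneous conformation c_hat of N
// dumbbells in D = 1, in bead coordinates (x_mu, y_mu) with the admissible
// domain 0 <= x <= 2 d2, max(2 d1 - x, 0) <= y <= 2 d2 - x (wall + slab).
// The histogram axis is c_hat = sum (y - x)^2 / N on [0, c_max], which the
// domain bounds by c2 = 4 d2^2. Modification factor schedule: classic
// halving on flatness until ln f falls below 1/t (t = steps / n_bins),
// then ln f = 1/t down to lnf_final.

static inline bool in_domain(double x, double y, double d1, double d2) {
  if (x < 0.0 || x > 2.0 * d2) return false;
  double lo = 2.0 * d1 - x;
  if (lo < 0.0) lo = 0.0;
  return y >= lo && y <= 2.0 * d2 - x;
}

// [[Rcpp::export]]
List wl_run_cpp(int N, double d1, double d2, double c_max, int n_bins,
                double step, double flatness, int check_every,
                double lnf_init, double lnf_final, double max_steps) {
  RNGScope scope;
  std::vector<double> x(N), y(N);
  double mid = (d1 + d2) / 2.0;
  for (int i = 0; i < N; ++i) { x[i] = mid; y[i] = mid; }
  double chat = 0.0;
  double wid = c_max / n_bins;

  NumericVector lnG(n_bins, 0.0);
  NumericVector H(n_bins, 0.0);
  NumericVector H_total(n_bins, 0.0);
  std::vector<double> lnf_trace;
  double lnf = lnf_init;
  lnf_trace.push_back(lnf);
  bool stage_tinv = false;
  bool converged = false;
  double steps = 0.0;
  int cur = 0;  // bin of chat = 0
  int recompute_counter = 0;

  while (steps < max_steps) {
    for (int it = 0; it < check_every; ++it) {
      steps += 1.0;
      int j = (int)(unif_rand() * 2 * N);
      if (j >= 2 * N) j = 2 * N - 1;
      int mu = j % N;
      bool move_x = j < N;
      double xm = x[mu], ym = y[mu];
      double xn = xm, yn = ym;
      double delta = (unif_rand() * 2.0 - 1.0) * step;
      if (move_x) xn += delta; else yn += delta;
      bool ok = in_domain(xn, yn, d1, d2);
      if (ok) {
        double qo = ym - xm, qn = yn - xn;
        double cnew = chat + (qn * qn - qo * qo) / N;
        if (cnew < 0.0) cnew = 0.0;
        int nb = (int)(cnew / wid);
        if (nb >= n_bins) {
          if (cnew <= c_max + 1e-9) nb = n_bins - 1; else ok = false;
        }
        if (ok) {
          double dl = lnG[cur] - lnG[nb];
          if (dl >= 0.0 || unif_rand() < std::exp(dl)) {
            x[mu] = xn; y[mu] = yn; chat = cnew; cur = nb;
          }
        }
      }
      lnG[cur] += lnf;
      H[cur] += 1.0;
      H_total[cur] += 1.0;
    }
    // guard against floating-point drift of the incremental c_hat
    if (++recompute_counter >= 1000) {
      recompute_counter = 0;
      double s = 0.0;
      for (int i = 0; i < N; ++i) {
        double q = y[i] - x[i];
        s += q * q;
      }
      chat = s / N;
      int nb = (int)(chat / wid);
      cur = nb >= n_bins ? n_bins - 1 : nb;
    }
    double t = steps / n_bins;
    if (!stage_tinv) {
      // flatness over bins ever visited: bins outside the reachable
      // range (e.g. above c2 when c_max exceeds it) cannot count
      double hmin = R_PosInf, hmax = 0.0;
      for (int b = 0; b < n_bins; ++b) {
        if (H_total[b] <= 0.0) continue;
        if (H[b] < hmin) hmin = H[b];
        if (H[b] > hmax) hmax = H[b];
      }
      if (hmax > 0.0 && hmin >= flatness * hmax) {
        lnf /= 2.0;
        std::fill(H.begin(), H.end(), 0.0);
        if (lnf <= 1.0 / t) {
          stage_tinv = true;
          lnf = 1.0 / t;
        }
        lnf_trace.push_back(lnf);
      }
    } else {
      lnf = 1.0 / t;
      if (lnf < 0.99 * lnf_trace.back()) lnf_trace.push_back(lnf);
    }
    if (lnf <= lnf_final) { converged = true; break; }
  }
  if (converged && lnf_trace.back() != lnf) lnf_trace.push_back(lnf);

  return List::create(
    _["lnG"] = lnG, _["H"] = H, _["H_total"] = H_total,
    _["ln_f"] = lnf, _["lnf_trace"] = NumericVector(lnf_trace.begin(),
                                                    lnf_trace.end()),
    _["stage"] = stage_tinv ? "t-inverse" : "flatness",
    _["mc_steps"] = steps, _["converged"] = converged,
    _["x"] = NumericVector(x.begin(), x.end()),
    _["y"] = NumericVector(y.begin(), y.end()), _["c_hat"] = chat);
}

// Fixed-weight reference walk: same move set, but the bias table lnG is
// supplied and never updated. With the exact log density-of-states the
// visit histogram is asymptotically flat; used to validate detailed
// balance and the binning independently of the WL update rule.
// [[Rcpp::export]]
List wl_reference_walk_cpp(int N, double d1, double d2, double c_max,
                           NumericVector lnG_fixed, double step,
                           double n_steps) {
  RNGScope scope;
  int n_bins = lnG_fixed.size();
  std::vector<double> x(N), y(N);
  double mid = (d1 + d2) / 2.0;
  for (int i = 0; i < N; ++i) { x[i] = mid; y[i] = mid; }
  double chat = 0.0;
  double wid = c_max / n_bins;
  NumericVector H(n_bins, 0.0);
  int cur = 0;
  for (double s = 0.0; s < n_steps; s += 1.0) {
    int j = (int)(unif_rand() * 2 * N);
    if (j >= 2 * N) j = 2 * N - 1;
    int mu = j % N;
    bool move_x = j < N;
    double xm = x[mu], ym = y[mu];
    double xn = xm, yn = ym;
    double delta = (unif_rand() * 2.0 - 1.0) * step;
    if (move_x) xn += delta; else yn += delta;
    if (in_domain(xn, yn, d1, d2)) {
      double qo = ym - xm, qn = yn - xn;
      double cnew = chat + (qn * qn - qo * qo) / N;
      if (cnew < 0.0) cnew = 0.0;
      int nb = (int)(cnew / wid);
      if (nb >= n_bins && cnew <= c_max + 1e-9) nb = n_bins - 1;
      if (nb < n_bins) {
        double dl = lnG_fixed[cur] - lnG_fixed[nb];
        if (dl >= 0.0 || unif_rand() < std::exp(dl)) {
          x[mu] = xn; y[mu] = yn; chat = cnew; cur = nb;
        }
      }
    }
    H[cur] += 1.0;
  }
  return List::create(_["H"] = H);
}
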