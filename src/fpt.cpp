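#include <Rcpp.h>
using namespace Rcpp;

// Exact sampler for the first-passage time of a Wiener process with drift v,
// diffusion coefficient s, absorbing boundaries {0, a} and unbiased start
// a/2. With a symmetric start the decision-time distribution conditional on
// the absorbing boundary is the same for both boundaries (the two defective
// densities differ only by a constant factor), so correctness is drawn as
// Bernoulli(P(upper)) and the time from the common conditional CDF by grid
// inversion of the large-time series (odd terms only at z = a/2).

namespace {

const int GRID_N = 2048;
const double TERM_EPS = 1e-14;

// Tail sum T(t) = sum over odd k of sgn_k * (k / lam_k) * exp(-lam_k * t)
// with sgn_k = sin(k*pi/2) = +1, -1, +1, ... and
// lam_k = 0.5 * (v^2/s^2 + k^2 * pi^2 * s^2 / a^2).
// The conditional decision-time CDF is F(t) = 1 - T(t) / T(0), and T(0) has
// the closed form (a^2 / (pi s^2)) * exp(-v a / (2 s^2)) / (1 + exp(-v a / s^2))
// obtained from the absorption probability, so the slowly converging t = 0
// series is never evaluated directly.
double tail_sum(double t, double vv, double c2) {
  double tot = 0.0;
  double sgn = 1.0;
  for (long k = 1; k < 2000000; k += 2) {
    double kk = static_cast<double>(k);
    double lam = 0.5 * (vv + kk * kk * c2);
    double term = kk / lam * std::exp(-lam * t);
    tot += sgn * term;
    sgn = -sgn;
    if (term < TERM_EPS) break; // alternating series: error < next term
  }
  return tot;
}

} // namespace

// [[Rcpp::export(name = ".fpt_sample_cells")]]
List fpt_sample_cells_cpp(IntegerVector n_trials, NumericVector drift_v,
                          NumericVector boundary_a, double s) {
  int ncell = n_trials.size();
  if (drift_v.size() != ncell || boundary_a.size() != ncell)
    stop("drift_v and boundary_a must have one entry per cell");
  if (!(s > 0.0)) stop("scaling s must be positive");
  long total = 0;
  for (int i = 0; i < ncell; ++i) {
    if (n_trials[i] < 1) stop("each cell needs at least one trial");
    total += n_trials[i];
  }
  NumericVector rt(total);
  IntegerVector upper(total);

  std::vector<double> tg(GRID_N + 1), Fg(GRID_N + 1);
  long pos = 0;
  for (int i = 0; i < ncell; ++i) {
    double v = drift_v[i], a = boundary_a[i];
    if (!(a > 0.0)) stop("boundary_a must be positive");
    if (!R_finite(v) || !R_finite(a)) stop("non-finite diffusion parameters");
    double s2 = s * s;
    double vv = v * v / s2;
    double c2 = M_PI * M_PI * s2 / (a * a);
    double lam1 = 0.5 * (vv + c2);
    double y = std::exp(-v * a / s2);
    double p_up = 1.0 / (1.0 + y);
    double T0 = a * a / (M_PI * s2) * std::exp(-v * a / (2.0 * s2)) / (1.0 + y);
    double tmax = 35.0 / lam1; // survival mass beyond tmax < 1e-13

    // conditional CDF on a quadratically spaced grid (dense near zero)
    tg[0] = 0.0;
    Fg[0] = 0.0;
    for (int j = 1; j <= GRID_N; ++j) {
      double fr = static_cast<double>(j) / GRID_N;
      double t = tmax * fr * fr;
      double F = 1.0 - tail_sum(t, vv, c2) / T0;
      if (F < Fg[j - 1]) F = Fg[j - 1]; // guard against rounding wiggle
      if (F > 1.0) F = 1.0;
      tg[j] = t;
      Fg[j] = F;
    }

    for (int m = 0; m < n_trials[i]; ++m) {
      upper[pos] = (unif_rand() < p_up) ? 1 : 0;
      double u = unif_rand() * Fg[GRID_N];
      int lo = 0, hi = GRID_N;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (Fg[mid] < u) lo = mid; else hi = mid;
      }
      double dF = Fg[hi] - Fg[lo];
      rt[pos] = (dF > 0.0)
        ? tg[lo] + (u - Fg[lo]) / dF * (tg[hi] - tg[lo])
        : tg[hi];
      ++pos;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}
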