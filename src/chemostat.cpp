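// Monod chemostat dynamics for two organisms, two primary carbon sources
// and up to two cross-fed metabolites, wired per interaction motif.
// State vector: (s1, s2, mA, mB, mt1, mt2), all g/L.
//
// Per organism i the growth rate has up to two channels:
//   primary:   mu_i * prod over consumed primary resources of m/(k+m)
//              (two shared-essential carbon sources enter as a product)
//   crossfed:  mu_i * mt_partner/(k_mt + mt_partner)
// Resource consumption is the corresponding channel's growth divided by
// the yield ratio K; cross-fed metabolites are produced at rate
// k_sec * s_producer; every pool is diluted at rate D; primary resources
// flow in at the additive constant I.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct CParams {
  double mu1, mu2, D, IA, IB, k, k_mt, K, K_mt, k_sec;
  int P1, P2;       // bitmask of primary resources consumed: 1 = A, 2 = B
  bool X1, X2;      // org1 consumes mt2 / org2 consumes mt1
};

static inline double monod(double m, double k) {
  return (m > 0.0) ? m / (k + m) : 0.0;
}

static void rhs(const CParams &p, const double *y, double *dy) {
  const double s1 = y[0], s2 = y[1], mA = y[2], mB = y[3],
               t1 = y[4], t2 = y[5];
  double g1p = 0.0, g2p = 0.0;
  if (p.P1) {
    g1p = p.mu1;
    if (p.P1 & 1) g1p *= monod(mA, p.k);
    if (p.P1 & 2) g1p *= monod(mB, p.k);
  }
  if (p.P2) {
    g2p = p.mu2;
    if (p.P2 & 1) g2p *= monod(mA, p.k);
    if (p.P2 & 2) g2p *= monod(mB, p.k);
  }
  const double g1x = p.X1 ? p.mu1 * monod(t2, p.k_mt) : 0.0;
  const double g2x = p.X2 ? p.mu2 * monod(t1, p.k_mt) : 0.0;

  dy[0] = s1 * (g1p + g1x - p.D);
  dy[1] = s2 * (g2p + g2x - p.D);

  const bool useA = (p.P1 & 1) || (p.P2 & 1);
  const bool useB = (p.P1 & 2) || (p.P2 & 2);
  dy[2] = (useA ? p.IA : 0.0) - p.D * mA;
  if (p.P1 & 1) dy[2] -= (s1 / p.K) * g1p;
  if (p.P2 & 1) dy[2] -= (s2 / p.K) * g2p;
  dy[3] = (useB ? p.IB : 0.0) - p.D * mB;
  if (p.P1 & 2) dy[3] -= (s1 / p.K) * g1p;
  if (p.P2 & 2) dy[3] -= (s2 / p.K) * g2p;

  dy[4] = p.X2 ? p.k_sec * s1 - (s2 / p.K_mt) * g2x - p.D * t1 : 0.0;
  dy[5] = p.X1 ? p.k_sec * s2 - (s1 / p.K_mt) * g1x - p.D * t2 : 0.0;
}

// Cash-Karp embedded Runge-Kutta 4(5) with adaptive step size and
// non-negativity clipping (clip events counted).
static const double CK_A[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
   253.0 / 4096}};
static const double CK_B5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594,
                                0, 512.0 / 1771};
static const double CK_B4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 1.0 / 4};

static int integrate_to(const CParams &p, double *y, double t0, double t1,
                        double rtol, double atol, int *nclip) {
  const int n = 6;
  double t = t0;
  double h = std::min(0.1, t1 - t0);
  double kst[6][6], ytmp[6], y5[6], y4[6];
  int steps = 0;
  const int max_steps = 20000000;
  while (t < t1 - 1e-12) {
    if (++steps > max_steps) return 1;
    if (t + h > t1) h = t1 - t;
    rhs(p, y, kst[0]);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = y[i];
        for (int j = 0; j < s; ++j) acc += h * CK_A[s][j] * kst[j][i];
        ytmp[i] = acc;
      }
      rhs(p, ytmp, kst[s]);
    }
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double a5 = y[i], a4 = y[i];
      for (int s = 0; s < 6; ++s) {
        a5 += h * CK_B5[s] * kst[s][i];
        a4 += h * CK_B4[s] * kst[s][i];
      }
      y5[i] = a5; y4[i] = a4;
      double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(a5));
      double e = std::abs(a5 - a4) / sc;
      if (e > err) err = e;
    }
    if (!std::isfinite(err)) return 2;
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = y5[i];
        if (y[i] < 0.0) { y[i] = 0.0; ++(*nclip); }
      }
      double f = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, f);
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
    }
    if (h < 1e-10) return 3;
  }
  return 0;
}

static CParams unpack(const List &pars) {
  CParams p;
  p.mu1 = pars["mu1"]; p.mu2 = pars["mu2"]; p.D = pars["D"];
  p.IA = pars["I_A"];  p.IB = pars["I_B"];
  p.k = pars["k"];     p.k_mt = pars["k_mt"];
  p.K = pars["K"];     p.K_mt = pars["K_mt"];
  p.k_sec = pars["k_sec"];
  p.P1 = as<int>(pars["P1"]); p.P2 = as<int>(pars["P2"]);
  p.X1 = as<bool>(pars["X1"]); p.X2 = as<bool>(pars["X2"]);
  return p;
}

// [[Rcpp::export(name = ".chemostat_run")]]
List chemostat_run(List pars, NumericVector y0, NumericVector times,
                   double rtol = 1e-6, double atol = 1e-9) {
  CParams p = unpack(pars);
  if (y0.size() != 6) stop("state vector must have 6 entries");
  double y[6];
  for (int i = 0; i < 6; ++i) y[i] = y0[i];
  NumericMatrix out(times.size(), 6);
  int nclip = 0;
  double t = times[0];
  for (int i = 0; i < 6; ++i) out(0, i) = y[i];
  for (int ti = 1; ti < times.size(); ++ti) {
    int code = integrate_to(p, y, t, times[ti], rtol, atol, &nclip);
    if (code != 0)
      stop("chemostat integration failed (code %d) near t=%g", code, t);
    t = times[ti];
    for (int i = 0; i < 6; ++i) out(ti, i) = y[i];
  }
  colnames(out) = CharacterVector::create("s1", "s2", "mA", "mB",
                                          "mt1", "mt2");
  return List::create(Named("states") = out,
                      Named("n_clipped") = nclip);
}

// Boolean stability grid over (mu1, mu2): both organisms above
// `threshold` at t_end.
// [[Rcpp::export(name = ".chemostat_grid")]]
LogicalMatrix chemostat_grid(List pars, NumericVector y0,
                             NumericVector mu1_grid,
                             NumericVector mu2_grid,
                             double t_end, double threshold,
                             double rtol = 1e-6, double atol = 1e-9) {
  CParams base = unpack(pars);
  LogicalMatrix out(mu1_grid.size(), mu2_grid.size());
  for (int i = 0; i < mu1_grid.size(); ++i) {
    for (int j = 0; j < mu2_grid.size(); ++j) {
      CParams p = base;
      p.mu1 = mu1_grid[i];
      p.mu2 = mu2_grid[j];
      double y[6];
      for (int s = 0; s < 6; ++s) y[s] = y0[s];
      int nclip = 0;
      int code = integrate_to(p, y, 0.0, t_end, rtol, atol, &nclip);
      if (code != 0)
        stop("chemostat integration failed (code %d) at cell (%d,%d)",
             code, i + 1, j + 1);
      out(i, j) = (y[0] >= threshold) && (y[1] >= threshold);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
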