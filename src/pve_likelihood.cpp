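// Marginal likelihood of the two-tissue mixture with a uniform
// concentration prior: the hot loop of the intensity update.
//
//   p(y | a, b, s) = [Phi((y-b)/s) - Phi((y-a)/s)] / (a - b)
//
// Parametrized as u = mu_wm - min(y), v = max(y) - mu_gm, ls = log(s).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475244;

// Phi(z1) - Phi(z2) for z1 > z2, via the numerically favourable tail
static inline double phi_diff(double z1, double z2) {
  if (z1 + z2 > 0.0)
    return 0.5 * (std::erfc(z2 * INV_SQRT2) - std::erfc(z1 * INV_SQRT2));
  return 0.5 * (std::erfc(-z1 * INV_SQRT2) - std::erfc(-z2 * INV_SQRT2));
}

// [[Rcpp::export(name = ".pve_nll_cpp")]]
double pve_nll_cpp(NumericVector par, NumericVector y, double lo, double hi) {
  const double u = par[0], v = par[1], s = std::exp(par[2]);
  const double b = lo + u, a = hi - v, delta = a - b;
  if (!std::isfinite(delta) || delta <= 1e-8) return 1e12;
  const int n = y.size();
  double nll = n * std::log(delta);
  for (int i = 0; i < n; ++i) {
    const double z1 = (y[i] - b) / s, z2 = (y[i] - a) / s;
    double P = phi_diff(z1, z2);
    if (P < 1e-290) {
      // deep tail: log-space fallback through R's pnorm
      const double l1 = R::pnorm(z1, 0.0, 1.0, 1, 1);
      const double l2 = R::pnorm(z2, 0.0, 1.0, 1, 1);
      const double d = l2 - l1;
      const double lp = l1 + std::log1p(-(d > -1e-16 ? 1.0 - 1e-16 : std::exp(d)));
      if (!std::isfinite(lp)) return 1e12;
      nll -= lp;
    } else {
      nll -= std::log(P);
    }
  }
  return std::isfinite(nll) ? nll : 1e12;
}

// [[Rcpp::export(name = ".pve_nll_grad_cpp")]]
NumericVector pve_nll_grad_cpp(NumericVector par, NumericVector y,
                               double lo, double hi) {
  const double u = par[0], v = par[1], s = std::exp(par[2]);
  const double b = lo + u, a = hi - v, delta = a - b;
  NumericVector g(3);
  if (!std::isfinite(delta) || delta <= 1e-8) return g;
  const int n = y.size();
  double du = 0.0, dv = 0.0, dls = 0.0;
  for (int i = 0; i < n; ++i) {
    const double z1 = (y[i] - b) / s, z2 = (y[i] - a) / s;
    double P = phi_diff(z1, z2);
    if (P < 1e-300) P = 1e-300;
    const double f1 = R::dnorm(z1, 0.0, 1.0, 0);
    const double f2 = R::dnorm(z2, 0.0, 1.0, 0);
    du += f1 / P;
    dv += f2 / P;
    dls -= (z2 * f2 - z1 * f1) / P;
  }
  g[0] = du / s - n / delta;
  g[1] = dv / s - n / delta;
  g[2] = dls;
  for (int k = 0; k < 3; ++k) if (!std::isfinite(g[k])) g[k] = 0.0;
  return g;
}
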