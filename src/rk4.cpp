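#include <Rcpp.h>
using namespace Rcpp;

// Logistic-minus-offset response G(x) = 1/(1+exp(-m(x-theta))) - 1/(1+exp(m*theta)).
// Plain evaluation is overflow-safe: exp() saturating to Inf gives 0, to 0 gives 1.
static inline double wc_G(double x, double m, double theta) {
  return 1.0 / (1.0 + std::exp(-m * (x - theta))) - 1.0 / (1.0 + std::exp(m * theta));
}

struct WCPars {
  double tau_E, tau_I, W_EE, W_II, W_EI, W_IE, i_E, i_I, m_E, m_I, th_E, th_I;
};

static inline void wc_field(const WCPars &p, double rE, double rI,
                            double &dE, double &dI) {
  double cE = p.W_EE * rE - p.W_EI * rI + p.i_E;
  double cI = p.W_IE * rE - p.W_II * rI + p.i_I;
  dE = (-rE + wc_G(cE, p.m_E, p.th_E)) / p.tau_E;
  dI = (-rI + wc_G(cI, p.m_I, p.th_I)) / p.tau_I;
}

// Classical fixed-step RK4 for the planar Wilson-Cowan system.
// pars must hold, in order: tau_E, tau_I, W_EE, W_II, W_EI, W_IE,
// i_E, i_I, m_E, m_I, theta_E, theta_I.
// Returns an (n_steps + 1) x 2 matrix of (r_E, r_I).
// [[Rcpp::export(name = ".wc_rk4_cpp")]]
NumericMatrix wc_rk4_cpp(NumericVector pars, NumericVector ic,
                         int n_steps, double dt) {
  if (pars.size() != 12) stop("internal: expected 12 packed parameters");
  WCPars p = {pars[0], pars[1], pars[2],  pars[3],  pars[4],  pars[5],
              pars[6], pars[7], pars[8],  pars[9],  pars[10], pars[11]};
  NumericMatrix out(n_steps + 1, 2);
  double rE = ic[0], rI = ic[1];
  out(0, 0) = rE;
  out(0, 1) = rI;
  double k1E, k1I, k2E, k2I, k3E, k3I, k4E, k4I;
  for (int i = 1; i <= n_steps; ++i) {
    wc_field(p, rE, rI, k1E, k1I);
    wc_field(p, rE + 0.5 * dt * k1E, rI + 0.5 * dt * k1I, k2E, k2I);
    wc_field(p, rE + 0.5 * dt * k2E, rI + 0.5 * dt * k2I, k3E, k3I);
    wc_field(p, rE + dt * k3E, rI + dt * k3I, k4E, k4I);
    rE += dt / 6.0 * (k1E + 2.0 * k2E + 2.0 * k3E + k4E);
    rI += dt / 6.0 * (k1I + 2.0 * k2I + 2.0 * k3I + k4I);
    if (!std::isfinite(rE) || !std::isfinite(rI))
      stop("integration blew up at step %d (t = %g s)", i, i * dt);
    out(i, 0) = rE;
    out(i, 1) = rI;
  }
  return out;
}
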