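#include <Rcpp.h>
using namespace Rcpp;

static inline double sigm_c(double v, double e0, double s0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (s0 - v)));
}

// Right-hand side of the 8-dimensional first-order system.
// State layout: y0..y3, dy0..dy3.  C = (C1..C7).
static void nmm_rhs(const double* y, double p,
                    double A, double B, double G,
                    double a, double b, double g,
                    const double* C, double e0, double s0, double r,
                    double* d) {
  const double v = C[1] * y[1] - C[3] * y[2] - C[6] * y[3];
  d[0] = y[4];
  d[1] = y[5];
  d[2] = y[6];
  d[3] = y[7];
  d[4] = A * a * sigm_c(v, e0, s0, r) - 2.0 * a * y[4] - a * a * y[0];
  d[5] = A * a * (sigm_c(C[0] * y[0], e0, s0, r) + p / C[1]) - 2.0 * a * y[5] - a * a * y[1];
  d[6] = B * b * sigm_c(C[2] * y[0], e0, s0, r) - 2.0 * b * y[6] - b * b * y[2];
  // Fast somatic inhibition: the fast interneurons see the slow-inhibitory
  // postsynaptic potential (y2), per the original five-state Wendling layout.
  d[7] = G * g * sigm_c(C[4] * y[0] - C[5] * y[2], e0, s0, r) - 2.0 * g * y[7] - g * g * y[3];
}

// Fixed-step RK4 with the exogenous drive held constant within each step.
// Returns the pyramidal membrane potential series and the final state.
// [[Rcpp::export]]
List nmm_rk4_cpp(NumericVector state0, NumericVector p, double dt,
                 double A, double B, double G,
                 double a, double b, double g,
                 NumericVector C, double e0, double s0, double r,
                 double blow_threshold) {
  const int n = p.size();
  double st[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int j = 0; j < 8; ++j) st[j] = state0[j];
  NumericVector out(n);
  int diverged_at = -1;
  const double* Cp = C.begin();

  for (int i = 0; i < n; ++i) {
    const double pp = p[i];
    nmm_rhs(st, pp, A, B, G, a, b, g, Cp, e0, s0, r, k1);
    for (int j = 0; j < 8; ++j) tmp[j] = st[j] + 0.5 * dt * k1[j];
    nmm_rhs(tmp, pp, A, B, G, a, b, g, Cp, e0, s0, r, k2);
    for (int j = 0; j < 8; ++j) tmp[j] = st[j] + 0.5 * dt * k2[j];
    nmm_rhs(tmp, pp, A, B, G, a, b, g, Cp, e0, s0, r, k3);
    for (int j = 0; j < 8; ++j) tmp[j] = st[j] + dt * k3[j];
    nmm_rhs(tmp, pp, A, B, G, a, b, g, Cp, e0, s0, r, k4);
    for (int j = 0; j < 8; ++j)
      st[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    out[i] = C[1] * st[1] - C[3] * st[2] - C[6] * st[3];
    bool bad = false;
    for (int j = 0; j < 8; ++j)
      if (!std::isfinite(st[j]) || std::fabs(st[j]) > blow_threshold) bad = true;
    if (bad) { diverged_at = i + 1; break; }
  }
  NumericVector fin(8);
  for (int j = 0; j < 8; ++j) fin[j] = st[j];
  return List::create(_["output"] = out, _["state"] = fin,
                      _["diverged_at"] = diverged_at);
}
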