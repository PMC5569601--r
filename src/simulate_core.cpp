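#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler time march of the coupled gastric/intestinal model.
//
// Gastric compartment (stirred tank): nutrient, liquid and thickener masses,
// with viscosity-driven secretion feeding the liquid pool.  Intestine:
// backward-difference upwind advection with first-order luminal absorption on
// a uniform grid over [0, L]; nutrient emptied from the stomach enters as a
// point bolus at z = l0.  The duodenal brake gates the emptying rate on the
// instantaneous intestinal absorption rate (field of the previous step).
//
// Mass bookkeeping uses the trapezoidal integral of the linear density; the
// advective outflow through z = L is the flux of the last trapezoid panel,
// u*dt*(s[N-1]+s[N])/2, which makes the per-step discrete balance
//   delta(intestinal mass) = injected - absorbed - outflow
// hold to round-off.

static inline double trapz_mass(const std::vector<double>& s, double dz) {
  const int n = (int)s.size();
  double acc = 0.5 * (s[0] + s[n - 1]);
  for (int j = 1; j < n - 1; ++j) acc += s[j];
  return acc * dz;
}

static inline double eval_gamma0(int form, double m_mu, double m_s,
                                 double m_sec, double C1, double mu,
                                 double V, double Ksec) {
  switch (form) {
  case 0: return C1;                       // constant emptying rate
  case 1: return m_mu * mu + m_s * V;      // viscosity + volume
  case 2: return m_s * V + C1;             // volume + constant
  case 3: return m_mu * mu + C1;           // viscosity + constant
  case 4: return m_sec * Ksec + C1;        // secretion + constant
  case 5: return m_sec * Ksec + m_s * V;   // secretion + volume
  default: return C1;
  }
}

static inline double eval_switch(double A, double gamma0, double A_max,
                                 double tau_A, bool smooth) {
  if (!R_FINITE(A_max)) return gamma0;     // brake disabled
  if (!smooth) return (A > A_max) ? 0.0 : gamma0;
  double x = tau_A * (A - A_max);
  if (x > 700.0) return 0.0;
  if (x < -700.0) return gamma0;
  return gamma0 / (1.0 + std::exp(x));
}

// [[Rcpp::export]]
List simulate_core_cpp(double stomN0, double liq0, double lbg0,
                       double aL, double bL, double rho_w,
                       bool has_secretion, double lambda_s, double b_exp,
                       double S_b,
                       int hyp_form, double m_mu, double m_s, double m_sec,
                       double C1,
                       double A_max, double tau_A, bool smooth_switch,
                       double Ka, double L, double u_bar, double dz,
                       double l0,
                       double dt, int n_steps, int every) {
  const int N = (int)std::lround(L / dz);   // nodes 0..N
  std::vector<double> s(N + 1, 0.0);
  int inj = (int)std::lround(l0 / dz);
  if (inj < 2) inj = 2;                     // keep the inlet ghost region empty
  if (inj > N - 1) inj = N - 1;

  const double cfl = u_bar * dt / dz;
  if (cfl + Ka * dt > 1.0) {
    return List::create(_["ok"] = false,
                        _["reason"] = "transport_stability",
                        _["dt_admissible"] = 1.0 / (u_bar / dz + Ka));
  }

  double stomN = stomN0, liq = liq0, lbg = lbg0;
  double cum_abs = 0.0, cum_out = 0.0, cum_sec = 0.0;

  const int n_rec = n_steps / every + 1;
  NumericVector r_t(n_rec), r_N(n_rec), r_liq(n_rec), r_lbg(n_rec),
      r_mu(n_rec), r_ks(n_rec), r_g0(n_rec), r_g(n_rec), r_A(n_rec),
      r_cabs(n_rec), r_cout(n_rec), r_csec(n_rec);
  int rec = 0;

  bool ok = true;
  bool field_active = false;
  std::string reason = "";
  double t = 0.0;

  for (int step = 0; step <= n_steps; ++step) {
    // algebraic state
    double conc = (liq > 0.0) ? 100.0 * lbg * rho_w / liq : 0.0; // g / 100 ml
    double mu = (conc > 0.0) ? aL * std::pow(conc, bL) : 0.0;
    double Ksec = has_secretion ? lambda_s * std::pow(mu, b_exp) + S_b : 0.0;
    double Vtot = (stomN + liq + lbg) / rho_w * 1e-6;            // m^3
    double g0 = eval_gamma0(hyp_form, m_mu, m_s, m_sec, C1, mu, Vtot, Ksec);
    double A = field_active ? Ka * trapz_mass(s, dz) : 0.0;
    double g = eval_switch(A, g0, A_max, tau_A, smooth_switch);

    if (step % every == 0 && rec < n_rec) {
      r_t[rec] = t; r_N[rec] = stomN; r_liq[rec] = liq; r_lbg[rec] = lbg;
      r_mu[rec] = mu; r_ks[rec] = Ksec; r_g0[rec] = g0; r_g[rec] = g;
      r_A[rec] = A; r_cabs[rec] = cum_abs; r_cout[rec] = cum_out;
      r_csec[rec] = cum_sec;
      ++rec;
    }
    if (step == n_steps) break;

    if (g * dt >= 1.0) { ok = false; reason = "gastric_stability"; break; }

    // gastric forward Euler
    double emptied_n = g * stomN * dt;
    stomN -= emptied_n;
    liq += dt * (Ksec - g * liq);
    lbg -= dt * g * lbg;
    cum_sec += Ksec * dt;

    // bolus injection, then upwind transport (skipped while the lumen has
    // never received mass — e.g. non-nutrient meals)
    if (emptied_n > 0.0) field_active = true;
    if (field_active) {
      s[inj] += emptied_n / dz;
      double absorbed = dt * Ka * trapz_mass(s, dz);
      double outflow = u_bar * dt * 0.5 * (s[N - 1] + s[N]);
      for (int j = N; j >= 1; --j)
        s[j] = s[j] - cfl * (s[j] - s[j - 1]) - Ka * dt * s[j];
      s[0] = s[1];
      cum_abs += absorbed;
      cum_out += outflow;
    }

    if (!R_FINITE(stomN) || !R_FINITE(liq) || stomN < -1e-12 ||
        liq < -1e-12 || lbg < -1e-12) {
      ok = false; reason = "negative_or_nan_state"; break;
    }
    t += dt;
  }

  return List::create(
      _["ok"] = ok, _["reason"] = reason, _["n_recorded"] = rec,
      _["time_s"] = r_t, _["nutrient_g"] = r_N, _["liquid_g"] = r_liq,
      _["thickener_g"] = r_lbg, _["viscosity_pa_s"] = r_mu,
      _["secretion_g_s"] = r_ks, _["gamma0_per_s"] = r_g0,
      _["gamma_per_s"] = r_g, _["absorption_g_s"] = r_A,
      _["cum_absorbed_g"] = r_cabs, _["cum_outflow_g"] = r_cout,
      _["cum_secreted_g"] = r_csec,
      _["field"] = NumericVector(s.begin(), s.end()));
}
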