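#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Units: mV, ms, uS, nF, nA. Rate functions are 1/ms.
// Gate update is Rush-Larsen (exact exponential relaxation toward the
// steady state implied by the voltage at the start of the step); the
// voltage update is backward Euler on the branched cable with a Hines
// elimination (parents are ordered before children).

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity at x = 0 patched
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct HcnPars {
  double v_half, slope, rate_max, mult_alpha, mult_beta, offset;
};

static inline void hcn_rates_c(double v, const HcnPars &p, double &a, double &b) {
  double x = (v - p.offset - p.v_half) / p.slope;
  a = p.mult_alpha * p.rate_max / (1.0 + std::exp(x));
  b = p.mult_beta * p.rate_max / (1.0 + std::exp(-x));
}

static inline void na_rates_c(double v, double shift, double h_shift,
                              double &am, double &bm, double &ah, double &bh) {
  double vs = v - shift;
  double vh = v - h_shift;
  am = 0.1 * vtrap(-(vs + 40.0), 10.0);
  bm = 4.0 * std::exp(-(vs + 65.0) / 18.0);
  ah = 0.07 * std::exp(-(vh + 65.0) / 20.0);
  bh = 1.0 / (1.0 + std::exp(-(vh + 35.0) / 10.0));
}

static inline void kdr_rates_c(double v, double shift, double rate_mult,
                               double &an, double &bn) {
  double vs = v - shift;
  an = rate_mult * 0.01 * vtrap(-(vs + 55.0), 10.0);
  bn = rate_mult * 0.125 * std::exp(-(vs + 65.0) / 80.0);
}

struct NaPPars { double frac, v_half, slope, tau; };

static inline double nap_inf(double v, const NaPPars &p) {
  return 1.0 / (1.0 + std::exp(-(v - p.v_half) / p.slope));
}

static inline double rl_step(double x, double a, double b, double dt) {
  double s = a + b;
  if (s <= 0) return x;
  double xinf = a / s;
  return xinf + (x - xinf) * std::exp(-dt * s);
}

// [[Rcpp::export]]
List cable_advance_cpp(NumericVector v0, NumericMatrix gates0,
                       IntegerVector parent, NumericVector g_ax,
                       NumericVector cm, NumericVector g_leak,
                       NumericVector gbar_na, NumericVector gbar_k,
                       NumericVector gbar_hcn,
                       double e_leak, double e_na, double e_k, double e_hcn,
                       double na_shift, double na_h_shift, double kdr_shift,
                       double kdr_rate_mult,
                       NumericVector hcn_pars, NumericVector nap_pars,
                       double dt, int n_steps,
                       IntegerVector syn_comp, NumericMatrix g_syn,
                       double e_ampa,
                       NumericVector i_inj,
                       IntegerVector clamp_comps, NumericVector clamp_v,
                       double g_clamp,
                       IntegerVector record_comp, int record_every) {
  int n = v0.size();
  int n_syn = syn_comp.size();
  int n_rec = record_comp.size();
  int n_samples = n_steps / record_every;

  HcnPars hp = {hcn_pars[0], hcn_pars[1], hcn_pars[2],
                hcn_pars[3], hcn_pars[4], hcn_pars[5]};
  NaPPars np = {nap_pars[0], nap_pars[1], nap_pars[2], nap_pars[3]};

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> ph(n), m(n), h(n), nn(n), pp(n);
  for (int i = 0; i < n; i++) {
    ph[i] = gates0(i, 0); m[i] = gates0(i, 1);
    h[i] = gates0(i, 2);  nn[i] = gates0(i, 3);
    pp[i] = gates0(i, 4);
  }

  NumericMatrix vrec(n_samples, n_rec);
  NumericVector irec(n_samples);
  std::vector<double> diag(n), rhs(n), gsum(n), erev_g(n);

  for (int step = 0; step < n_steps; step++) {
    // gate update from previous-step voltage
    for (int i = 0; i < n; i++) {
      double vi = v[i];
      if (gbar_hcn[i] > 0) {
        double a, b; hcn_rates_c(vi, hp, a, b);
        ph[i] = rl_step(ph[i], a, b, dt);
      }
      if (gbar_na[i] > 0) {
        double am, bm, ah, bh;
        na_rates_c(vi, na_shift, na_h_shift, am, bm, ah, bh);
        m[i] = rl_step(m[i], am, bm, dt);
        h[i] = rl_step(h[i], ah, bh, dt);
        double pinf = nap_inf(vi, np);
        pp[i] = pinf + (pp[i] - pinf) * std::exp(-dt / np.tau);
      }
      if (gbar_k[i] > 0) {
        double an, bn; kdr_rates_c(vi, kdr_shift, kdr_rate_mult, an, bn);
        nn[i] = rl_step(nn[i], an, bn, dt);
      }
    }
    // ionic conductances for the implicit voltage step
    for (int i = 0; i < n; i++) {
      double g = g_leak[i];
      double ge = g_leak[i] * e_leak;
      if (gbar_na[i] > 0) {
        double gna = gbar_na[i] *
          (m[i] * m[i] * m[i] * h[i] + np.frac * pp[i]);
        g += gna; ge += gna * e_na;
      }
      if (gbar_k[i] > 0) {
        double n2 = nn[i] * nn[i];
        double gk = gbar_k[i] * n2 * n2;
        g += gk; ge += gk * e_k;
      }
      if (gbar_hcn[i] > 0) {
        double gh = gbar_hcn[i] * ph[i];
        g += gh; ge += gh * e_hcn;
      }
      gsum[i] = g; erev_g[i] = ge;
    }
    for (int s = 0; s < n_syn; s++) {
      int c = syn_comp[s];
      double gs = g_syn(step, s);
      gsum[c] += gs; erev_g[c] += gs * e_ampa;
    }
    double cmd = 0.0;
    for (int i = 0; i < n; i++) {
      diag[i] = cm[i] / dt + gsum[i];
      rhs[i] = cm[i] / dt * v[i] + erev_g[i] + i_inj[i];
    }
    int n_clamp = clamp_comps.size();
    if (n_clamp > 0) {
      cmd = clamp_v[step];
      for (int c = 0; c < n_clamp; c++) {
        diag[clamp_comps[c]] += g_clamp;
        rhs[clamp_comps[c]] += g_clamp * cmd;
      }
    }
    // axial coupling: add to both ends
    for (int i = 1; i < n; i++) {
      diag[i] += g_ax[i];
      diag[parent[i]] += g_ax[i];
    }
    // Hines elimination, children (higher index) into parents
    for (int i = n - 1; i >= 1; i--) {
      double f = g_ax[i] / diag[i];
      diag[parent[i]] -= f * g_ax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; i++) {
      v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / diag[i];
    }
    if ((step & 255) == 0) {
      for (int i = 0; i < n; i++) {
        if (!std::isfinite(v[i]))
          stop("voltage diverged (non-finite) in compartment %d at t = %g ms",
               i + 1, (step + 1) * dt);
      }
    }
    if ((step + 1) % record_every == 0) {
      int k = (step + 1) / record_every - 1;
      for (int r = 0; r < n_rec; r++) vrec(k, r) = v[record_comp[r]];
      if (n_clamp > 0) {
        double itot = 0.0;
        for (int c = 0; c < n_clamp; c++) {
          itot += g_clamp * (cmd - v[clamp_comps[c]]);
        }
        irec[k] = itot;
      }
    }
  }

  NumericVector vout(n);
  NumericMatrix gout(n, 5);
  for (int i = 0; i < n; i++) {
    vout[i] = v[i];
    gout(i, 0) = ph[i]; gout(i, 1) = m[i];
    gout(i, 2) = h[i];  gout(i, 3) = nn[i];
    gout(i, 4) = pp[i];
  }
  return List::create(_["v"] = vout, _["gates"] = gout,
                      _["vrec"] = vrec, _["irec"] = irec);
}

// Asymmetric first-order filter: dy/dt = (x - y)/tau with tau = tau_rise
// while the input exceeds the output and tau_fall otherwise; exact
// exponential update per sample.
// [[Rcpp::export]]
List filter_asym_cpp(NumericVector x, double dt, double tau_rise,
                     double tau_fall, double y0) {
  int n = x.size();
  NumericVector y(n);
  double yc = y0;
  double er = std::exp(-dt / tau_rise), ef = std::exp(-dt / tau_fall);
  for (int i = 0; i < n; i++) {
    double e = (x[i] > yc) ? er : ef;
    yc = x[i] + (yc - x[i]) * e;
    y[i] = yc;
  }
  return List::create(_["y"] = y, _["y_end"] = yc);
}

// Three-state AMPA receptor scheme, backward Euler (occupancy conserving):
//   C -- kon*glu --> O,  O -- koff --> C,
//   O -- kdes --> D,     D -- kres --> C
// States x = (C, O, D); returns the open-fraction trace.
// [[Rcpp::export]]
List ampa_integrate_cpp(NumericVector glu, double dt,
                        double kon, double koff, double kdes, double kres,
                        NumericVector state0) {
  int n = glu.size();
  NumericVector open(n);
  double C = state0[0], O = state0[1], D = state0[2];
  for (int i = 0; i < n; i++) {
    double a = kon * glu[i];
    // backward Euler: solve (I - dt*Q^T) x_new = x_old for 3 states
    // rows: C' = C - dt*(a*C' - koff*O' - kres*D')
    //       O' = O - dt*((koff+kdes)*O' - a*C')
    //       D' = D - dt*(kres*D' - kdes*O')
    double a11 = 1.0 + dt * a,            a12 = -dt * koff, a13 = -dt * kres;
    double a21 = -dt * a, a22 = 1.0 + dt * (koff + kdes),   a23 = 0.0;
    double a31 = 0.0,     a32 = -dt * kdes, a33 = 1.0 + dt * kres;
    double det = a11 * (a22 * a33 - a23 * a32)
               - a12 * (a21 * a33 - a23 * a31)
               + a13 * (a21 * a32 - a22 * a31);
    double Cn = (C * (a22 * a33 - a23 * a32)
               - a12 * (O * a33 - a23 * D)
               + a13 * (O * a32 - a22 * D)) / det;
    double On = (a11 * (O * a33 - a23 * D)
               - C * (a21 * a33 - a23 * a31)
               + a13 * (a21 * D - O * a31)) / det;
    double Dn = (a11 * (a22 * D - O * a32)
               - a12 * (a21 * D - O * a31)
               + C * (a21 * a32 - a22 * a31)) / det;
    C = Cn; O = On; D = Dn;
    open[i] = O;
  }
  return List::create(_["open"] = open,
                      _["state_end"] = NumericVector::create(C, O, D));
}
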