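// Stepped simulation kernels: pump speed/hydraulic dynamics, the
// 8-compartment cardiovascular model, the Lagrangian hemolysis particle
// scheme, and the single-rate coupled loop.  All kernels use clinical
// units at their interfaces (rpm, L/min, mmHg, s); the particle scheme
// converts flow to mL/s internally so that Vi/Q is a time in seconds.
#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mechanical subsystem: exact zero-order-hold recurrence of the PT2 closed
// loop, with the dead time realised as a ring buffer of past reference speeds.
// Ad (2x2) and Bd (2) are the discretized state matrices, precomputed in R.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mech_run(NumericVector n_ref, double dt, NumericMatrix Ad,
                  NumericVector Bd, NumericVector x0, int delay_steps) {
  int ns = n_ref.size();
  NumericVector n(ns);
  double x1 = x0[0], x2 = x0[1];
  for (int i = 0; i < ns; ++i) {
    n[i] = x1;
    double u = (i - delay_steps >= 0) ? n_ref[i - delay_steps] : n_ref[0];
    double nx1 = Ad(0, 0) * x1 + Ad(0, 1) * x2 + Bd[0] * u;
    double nx2 = Ad(1, 0) * x1 + Ad(1, 1) * x2 + Bd[1] * u;
    x1 = nx1; x2 = nx2;
  }
  return List::create(_["n"] = n, _["state"] = NumericVector::create(x1, x2));
}

// ---------------------------------------------------------------------------
// Hydraulic subsystem: explicit Euler on
//   L dQ/dt = a Q + b n^2 + c Q^x n^y - dP,   Q in L/min.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_hyd_run(NumericVector n, NumericVector dp, double dt, double L,
                 double a, double b, double c, double x, double y, double q0) {
  int ns = n.size();
  NumericVector q(ns);
  double Q = q0;
  for (int i = 0; i < ns; ++i) {
    q[i] = Q;
    double dQ = (a * Q + b * n[i] * n[i] + c * std::pow(Q, x) * std::pow(n[i], y)
                 - dp[i]) / L;
    Q += dQ * dt;
    if (!std::isfinite(Q))
      stop("hydraulic integration diverged at step %d (t = %g s)", i + 1,
           (i + 1) * dt);
  }
  return List::create(_["q"] = q, _["q_final"] = Q);
}

// ---------------------------------------------------------------------------
// Lagrangian particle scheme over the impeller region.
// Per step: inject one particle at l = 0 with HRI_l = 0; advance every
// particle by dl = Q * li/Vi * dt and accumulate HRI_l through the
// effective-time rule at the end-of-step speed; remove particles with
// l >= li (their HRI_l is the exit value); aggregate = f * mean(HRI_l).
// Particles are age-ordered, so exits always occur at the back.
// ---------------------------------------------------------------------------

struct ParticleField {
  std::deque<double> l, hri;  // front = newest
};

static inline void particle_step(ParticleField &pf, double q_lpm, double n,
                                 double dt, double c2hat, double a2hat,
                                 double b2, double vi, double li,
                                 std::vector<double> *exit_hri,
                                 std::vector<double> *exit_step, int step) {
  double q_mls = q_lpm * 1000.0 / 60.0;
  double dl = q_mls * li / vi * dt;
  double nb = std::pow(n, b2);
  double inv_a2 = 1.0 / a2hat;
  pf.l.push_front(0.0);
  pf.hri.push_front(0.0);
  size_t np = pf.l.size();
  for (size_t j = 0; j < np; ++j) {
    double h = pf.hri[j];
    double teff = (h > 0.0) ? std::pow(h / (c2hat * nb), inv_a2) : 0.0;
    pf.hri[j] = c2hat * std::pow(teff + dt, a2hat) * nb;
    pf.l[j] += dl;
  }
  while (!pf.l.empty() && pf.l.back() >= li) {
    if (exit_hri) {
      exit_hri->push_back(pf.hri.back());
      exit_step->push_back(step + 1);
    }
    pf.l.pop_back();
    pf.hri.pop_back();
  }
}

static inline double field_mean(const ParticleField &pf) {
  double s = 0.0;
  for (size_t j = 0; j < pf.hri.size(); ++j) s += pf.hri[j];
  return s / pf.hri.size();
}

// [[Rcpp::export]]
List cpp_lagrangian_run(NumericVector q_lpm, NumericVector n_rpm, double dt,
                        double c2hat, double a2hat, double b2, double vi,
                        double li, double f, NumericVector l0,
                        NumericVector hri0, bool log_exits) {
  int ns = q_lpm.size();
  if (n_rpm.size() != ns) stop("q and n series must have equal length");
  ParticleField pf;
  for (int j = 0; j < l0.size(); ++j) {
    pf.l.push_back(l0[j]);
    pf.hri.push_back(hri0[j]);
  }
  NumericVector hri(ns);
  IntegerVector count(ns);
  std::vector<double> ex_h, ex_s;
  for (int i = 0; i < ns; ++i) {
    if (!(q_lpm[i] > 0.0))
      stop("backflow or zero flow (Q = %g L/min) at step %d: the Lagrangian "
           "hemolysis model is only valid for forward flow", q_lpm[i], i + 1);
    particle_step(pf, q_lpm[i], n_rpm[i], dt, c2hat, a2hat, b2, vi, li,
                  log_exits ? &ex_h : (std::vector<double> *)0,
                  log_exits ? &ex_s : (std::vector<double> *)0, i);
    hri[i] = f * field_mean(pf);
    count[i] = pf.l.size();
  }
  List out = List::create(
      _["hri"] = hri, _["count"] = count,
      _["l_final"] = NumericVector(pf.l.begin(), pf.l.end()),
      _["hri_final"] = NumericVector(pf.hri.begin(), pf.hri.end()));
  if (log_exits) {
    out["exit_hri"] = NumericVector(ex_h.begin(), ex_h.end());
    out["exit_step"] = NumericVector(ex_s.begin(), ex_s.end());
  }
  return out;
}

// Run at constant (Q, n) until the particle population reaches its steady
// age distribution (one washout after start) and return the aggregate.
// [[Rcpp::export]]
List cpp_lagrangian_steady(double q_lpm, double n_rpm, double dt,
                           double c2hat, double a2hat, double b2, double vi,
                           double li, double f) {
  double q_mls = q_lpm * 1000.0 / 60.0;
  int washout_steps = (int)std::ceil(vi / (q_mls * dt));
  int ns = washout_steps + 10;
  ParticleField pf;
  double agg = NA_REAL, prev = NA_REAL;
  for (int i = 0; i < ns; ++i) {
    particle_step(pf, q_lpm, n_rpm, dt, c2hat, a2hat, b2, vi, li, 0, 0, i);
    prev = agg;
    agg = f * field_mean(pf);
  }
  if (!(std::fabs(agg - prev) <= 1e-9 * std::fabs(agg)))
    stop("particle aggregate failed to reach steady state");
  return List::create(_["hri"] = agg, _["count"] = (int)pf.l.size(),
                      _["washout_steps"] = washout_steps);
}

// ---------------------------------------------------------------------------
// Cardiovascular system: 8 compliance compartments (LV, LA, RV, RA, systemic
// arterial, systemic venous, pulmonary arterial, pulmonary venous), ideal
// diode valves with small series resistances, double-Hill time-varying
// ventricular elastance, passive atria, linear septal pressure coupling.
// Parameter vector layout (see cvs_params() in R):
//  0 ees_lv  1 ed_lv  2 v0_lv  3 ees_rv  4 ed_rv  5 v0_rv
//  6 c_la    7 v0_la  8 c_ra   9 v0_ra
// 10 c_sa   11 c_sv  12 c_pa  13 c_pv
// 14 r_mv   15 r_av  16 r_sys 17 r_vr  18 r_tv  19 r_pvalve
// 20 r_pul  21 r_pvla
// 22 k_sept 23 hr    24 cf_lv 25 f_rsys
// 26 act_a1 27 act_n1 28 act_a2 29 act_n2 30 act_norm
// ---------------------------------------------------------------------------

struct CvsOut { double pao, plv, q_av; };

static inline double activation(double phase, const double *p) {
  double g1 = std::pow(phase / p[26], p[27]);
  double g2 = std::pow(phase / p[28], p[29]);
  return (g1 / (1.0 + g1)) / (1.0 + g2) / p[30];
}

static inline CvsOut cvs_step(double *v, double phase, double q_lvad_mls,
                              double dt, const double *p, int step) {
  double act = activation(phase, p);
  double e_lv = p[1] + act * (p[24] * p[0] - p[1]);
  double e_rv = p[4] + act * (p[3] - p[4]);
  double plv_f = e_lv * (v[0] - p[2]);
  double prv_f = e_rv * (v[2] - p[5]);
  double plv = plv_f + p[22] * prv_f;
  double prv = prv_f + p[22] * plv_f;
  double pla = (v[1] - p[7]) / p[6];
  double pra = (v[3] - p[9]) / p[8];
  double psa = v[4] / p[10];
  double psv = v[5] / p[11];
  double ppa = v[6] / p[12];
  double ppv = v[7] / p[13];

  double q_mv = std::max(0.0, (pla - plv) / p[14]);
  double q_av = std::max(0.0, (plv - psa) / p[15]);
  double q_sys = (psa - psv) / (p[16] * p[25]);
  double q_vr = (psv - pra) / p[17];
  double q_tv = std::max(0.0, (pra - prv) / p[18]);
  double q_pvalve = std::max(0.0, (prv - ppa) / p[19]);
  double q_pul = (ppa - ppv) / p[20];
  double q_pvla = (ppv - pla) / p[21];

  v[0] += dt * (q_mv - q_av - q_lvad_mls);
  v[1] += dt * (q_pvla - q_mv);
  v[2] += dt * (q_tv - q_pvalve);
  v[3] += dt * (q_vr - q_tv);
  v[4] += dt * (q_av + q_lvad_mls - q_sys);
  v[5] += dt * (q_sys - q_vr);
  v[6] += dt * (q_pvalve - q_pul);
  v[7] += dt * (q_pul - q_pvla);
  for (int k = 0; k < 8; ++k) {
    if (!std::isfinite(v[k]))
      stop("cardiovascular state became non-finite at step %d", step + 1);
    if (v[k] < 0.0)
      stop("negative compartment volume (compartment %d) at step %d: "
           "reduce the step size or check the parameterization", k + 1,
           step + 1);
  }
  CvsOut out; out.pao = psa; out.plv = plv; out.q_av = q_av;
  return out;
}

// [[Rcpp::export]]
List cpp_cvs_run(NumericVector q_lvad_lpm, double dt, NumericVector par,
                 NumericVector v0, double phase0) {
  int ns = q_lvad_lpm.size();
  double v[8];
  for (int k = 0; k < 8; ++k) v[k] = v0[k];
  const double *p = par.begin();
  double phase = phase0;
  NumericVector pao(ns), plv(ns), q_av(ns), vol(ns);
  IntegerVector cycle(ns);
  int cyc = 0;
  for (int i = 0; i < ns; ++i) {
    CvsOut o = cvs_step(v, phase, q_lvad_lpm[i] * 1000.0 / 60.0, dt, p, i);
    pao[i] = o.pao; plv[i] = o.plv; q_av[i] = o.q_av * 60.0 / 1000.0;
    double tot = 0.0; for (int k = 0; k < 8; ++k) tot += v[k];
    vol[i] = tot;
    cycle[i] = cyc;
    phase += dt * p[23] / 60.0;
    if (phase >= 1.0) { phase -= 1.0; ++cyc; }
  }
  return List::create(_["pao"] = pao, _["plv"] = plv, _["q_av"] = q_av,
                      _["volume"] = vol, _["cycle"] = cycle,
                      _["v_final"] = NumericVector(v, v + 8),
                      _["phase_final"] = phase);
}

// ---------------------------------------------------------------------------
// Coupled single-rate loop (one global dt):
//   mech -> hydraulic (dP = pao - plv from the current CVS state)
//        -> CVS (driven by the new pump flow) -> particle scheme.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_coupled_run(NumericVector n_ref, double dt, NumericMatrix Ad,
                     NumericVector Bd, NumericVector x0, int delay_steps,
                     NumericVector hyd, double q0, NumericVector cvs_par,
                     NumericVector v0, double phase0, NumericVector hemo,
                     NumericVector l0, NumericVector hri0) {
  int ns = n_ref.size();
  double x1 = x0[0], x2 = x0[1];
  double L = hyd[0], a = hyd[1], b = hyd[2], c = hyd[3], xe = hyd[4],
         ye = hyd[5];
  double Q = q0;
  double v[8];
  for (int k = 0; k < 8; ++k) v[k] = v0[k];
  const double *p = cvs_par.begin();
  double phase = phase0;
  double c2hat = hemo[0], a2hat = hemo[1], b2 = hemo[2], vi = hemo[3],
         li = hemo[4], f = hemo[5];
  ParticleField pf;
  for (int j = 0; j < l0.size(); ++j) {
    pf.l.push_back(l0[j]);
    pf.hri.push_back(hri0[j]);
  }

  NumericVector n_s(ns), q_s(ns), dp_s(ns), pao_s(ns), plv_s(ns), hri_s(ns),
      qav_s(ns), vol_s(ns);
  IntegerVector cycle(ns), count(ns);
  int cyc = 0;

  // pressures from the initial volumes give the first head pressure
  double psa = v[4] / p[10];
  double act0 = activation(phase, p);
  double plv0 = (p[1] + act0 * (p[24] * p[0] - p[1])) * (v[0] - p[2]) +
                p[22] * ((p[4] + act0 * (p[3] - p[4])) * (v[2] - p[5]));
  double pao = psa, plv = plv0;

  for (int i = 0; i < ns; ++i) {
    // mechanical subsystem
    double n = x1;
    double u = (i - delay_steps >= 0) ? n_ref[i - delay_steps] : n_ref[0];
    double nx1 = Ad(0, 0) * x1 + Ad(0, 1) * x2 + Bd[0] * u;
    double nx2 = Ad(1, 0) * x1 + Ad(1, 1) * x2 + Bd[1] * u;
    x1 = nx1; x2 = nx2;
    // hydraulic subsystem, head pressure from the current CVS state
    double dp = pao - plv;
    double dQ = (a * Q + b * n * n + c * std::pow(Q, xe) * std::pow(n, ye)
                 - dp) / L;
    Q += dQ * dt;
    if (!std::isfinite(Q))
      stop("pump flow diverged at step %d (t = %g s)", i + 1, (i + 1) * dt);
    if (Q <= 0.0)
      stop("LVAD backflow (Q = %g L/min) at step %d (t = %g s): hemolysis is "
           "only evaluated for forward-flow conditions", Q, i + 1,
           (i + 1) * dt);
    // cardiovascular system
    CvsOut o = cvs_step(v, phase, Q * 1000.0 / 60.0, dt, p, i);
    pao = o.pao; plv = o.plv;
    // Lagrangian hemolysis
    particle_step(pf, Q, n, dt, c2hat, a2hat, b2, vi, li, 0, 0, i);

    n_s[i] = n; q_s[i] = Q; dp_s[i] = dp; pao_s[i] = pao; plv_s[i] = plv;
    hri_s[i] = f * field_mean(pf);
    qav_s[i] = o.q_av * 60.0 / 1000.0;
    double tot = 0.0; for (int k = 0; k < 8; ++k) tot += v[k];
    vol_s[i] = tot;
    cycle[i] = cyc; count[i] = pf.l.size();
    phase += dt * p[23] / 60.0;
    if (phase >= 1.0) { phase -= 1.0; ++cyc; }
  }
  return List::create(
      _["n"] = n_s, _["q"] = q_s, _["dp"] = dp_s, _["pao"] = pao_s,
      _["plv"] = plv_s, _["hri"] = hri_s, _["q_av"] = qav_s,
      _["volume"] = vol_s, _["cycle"] = cycle, _["count"] = count,
      _["v_final"] = NumericVector(v, v + 8), _["phase_final"] = phase,
      _["mech_final"] = NumericVector::create(x1, x2), _["q_final"] = Q);
}
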