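#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit-Euler integration of the 25-stock catchment model.
// This mirrors core_rates_vec() / core_aux_vec() in R/model.R operation for
// operation; the R functions are the reference implementation and a test
// asserts agreement. Parameter vector `v` uses the canonical order of
// param_names_flat() (0-based here); stocks use the order of stock_names().
//
// effects: matrix with columns (param index 1-based, mode 1=multiply
// 2=add 3=replace, magnitude, start_week, ramp_weeks); each effect ramps
// linearly from start over its ramp length.

static inline void effective_params(const double* v0, double* v, int np,
                                    const NumericMatrix& eff, double t) {
  for (int i = 0; i < np; ++i) v[i] = v0[i];
  const int ne = eff.nrow();
  if (ne == 0) return;
  for (int pass = 1; pass <= 3; ++pass) {
    for (int j = 0; j < ne; ++j) {
      if ((int) eff(j, 1) != pass) continue;
      double ramp = eff(j, 4);
      double phi;
      if (ramp <= 0.0) {
        phi = (t >= eff(j, 3)) ? 1.0 : 0.0;
      } else {
        phi = (t - eff(j, 3)) / ramp;
        if (phi < 0.0) phi = 0.0;
        if (phi > 1.0) phi = 1.0;
      }
      if (phi <= 0.0) continue;
      int i = (int) eff(j, 0) - 1;
      double m = eff(j, 2);
      if (pass == 1) {
        v[i] *= 1.0 + (m - 1.0) * phi;
      } else if (pass == 2) {
        v[i] += m * phi;
      } else {
        v[i] = v0[i] + (m - v0[i]) * phi;
      }
    }
  }
}

static inline void core_rates(const double* s, const double* v, double* r) {
  for (int i = 0; i < 25; ++i) r[i] = 0.0;
  double P = 0.0;
  for (int i = 0; i < 11; ++i) P += s[i];

  // population sector
  r[0] += v[1] * P;
  for (int i = 0; i < 11; ++i) r[i] += v[2] * s[i] - v[3] * s[i];

  // distress sector
  double onset = v[5] * s[0];
  r[0] -= onset; r[1] += onset;
  double recu = v[6] * s[1];
  r[1] -= recu; r[0] += recu;
  const int waitq[2] = {2, 4};
  for (int k = 0; k < 2; ++k) {
    int i = waitq[k];
    double f = v[6] * s[i];
    r[i] -= f; r[0] += f;
  }
  double recd = v[6] * v[45] * s[10];
  r[10] -= recd; r[0] += recd;
  const int incare[5] = {3, 5, 6, 7, 8};
  for (int k = 0; k < 5; ++k) {
    int i = incare[k];
    double f = v[7] * s[i];
    r[i] -= f; r[0] += f;
  }
  double pdout = s[9] / v[43];
  r[9] -= pdout;
  r[0] += v[44] * pdout;
  r[1] += (1.0 - v[44]) * pdout;

  // services sector
  double seek = v[8] * s[1];
  r[1] -= seek;
  r[8] += v[9] * seek;
  r[2] += (1.0 - v[9]) * seek;
  double reseek = v[8] * v[10] * s[10];
  r[10] -= reseek; r[2] += reseek;

  double gp_in = std::min(s[2] / v[33], s[12]);
  r[2] -= gp_in; r[3] += gp_in; r[20] += gp_in;

  double gp_out = s[3] / v[28];
  r[3] -= gp_out;
  r[4] += v[22] * gp_out;
  double cmhc_want = v[23] * gp_out;
  double cmhc_adm = std::min(cmhc_want, s[14]);
  r[6] += cmhc_adm; r[1] += cmhc_want - cmhc_adm;
  r[22] += cmhc_adm;
  double inpt_want = v[24] * gp_out;
  double inpt_free = std::max(0.0, (s[15] - s[7]) / v[33]);
  double inpt_adm = std::min(inpt_want, inpt_free);
  r[7] += inpt_adm; r[1] += inpt_want - inpt_adm;
  r[23] += inpt_adm;
  r[8] += v[25] * gp_out;
  double dis = v[26] * gp_out;
  r[0] += v[27] * dis;
  r[1] += (1.0 - v[27]) * dis;

  double sp_in = std::min(s[4] / v[33], s[13]);
  r[4] -= sp_in; r[5] += sp_in; r[21] += sp_in;

  double sp_out = s[5] / v[29];
  r[5] -= sp_out;
  r[0] += v[27] * sp_out; r[1] += (1.0 - v[27]) * sp_out;
  double cm_out = s[6] / v[30];
  r[6] -= cm_out;
  r[0] += v[27] * cm_out; r[1] += (1.0 - v[27]) * cm_out;
  double on_out = s[8] / v[31];
  r[8] -= on_out;
  r[0] += v[27] * on_out; r[1] += (1.0 - v[27]) * on_out;
  double ip_out = s[7] / v[32];
  r[7] -= ip_out; r[9] += ip_out;

  // disengagement
  double w_gp = (s[12] <= 0.0) ? v[37] : std::min(s[2] / s[12], v[37]);
  double w_sp = (s[13] <= 0.0) ? v[37] : std::min(s[4] / s[13], v[37]);
  double dg = s[2] * v[35] * w_gp / (w_gp + v[34]);
  double ds = s[4] * v[35] * w_sp / (w_sp + v[34]);
  r[2] -= dg; r[4] -= ds;
  r[10] += dg + ds;
  r[24] += dg + ds;
  const int dissat[4] = {3, 5, 6, 8};
  for (int k = 0; k < 4; ++k) {
    int i = dissat[k];
    double f = v[36] * s[i];
    r[i] -= f; r[10] += f;
    r[24] += f;
  }

  // suicidal behaviour sector
  double grate[11];
  grate[0] = 0.0;
  grate[1] = v[38]; grate[2] = v[38]; grate[4] = v[38]; grate[10] = v[38];
  grate[3] = v[39]; grate[5] = v[39]; grate[6] = v[39]; grate[7] = v[39];
  grate[8] = v[39];
  grate[9] = v[40];
  for (int i = 0; i < 11; ++i) {
    if (grate[i] <= 0.0) continue;
    double att = grate[i] * s[i];
    double deaths = v[42] * att;
    r[i] -= deaths;
    r[17] += deaths;
    double hosp_move = v[41] * (1.0 - v[42]) * att;
    if (i != 7) {
      r[i] -= hosp_move;
      r[7] += hosp_move;
      r[23] += hosp_move;
    }
    r[18] += v[41] * att;
  }
  r[19] += v[11] * (s[1] + s[2] + s[4] + s[9] + s[10]);

  // capacity growth
  r[12] = v[17] / 52.0 * s[12];
  r[13] = v[18] / 52.0 * s[13];
  r[14] = v[19] / 52.0 * s[14];
  r[15] = v[20] / 52.0 * s[15];
  r[16] = v[21] / 52.0 * s[16];

  // exact closure stock
  double tot = 0.0;
  for (int i = 0; i < 11; ++i) tot += r[i];
  r[11] = tot;
}

static inline void core_aux(const double* s, const double* v, double* a) {
  double P = 0.0;
  for (int i = 0; i < 11; ++i) P += s[i];
  a[0] = (P > 0.0) ? (P - s[0]) / P : 0.0;
  a[1] = (s[12] <= 0.0) ? v[37] : std::min(s[2] / s[12], v[37]);
  a[2] = (s[13] <= 0.0) ? v[37] : std::min(s[4] / s[13], v[37]);
}

// [[Rcpp::export]]
List sim_core_cpp(NumericVector v_base, NumericVector state0, int n_steps,
                  double dt, double t0, NumericMatrix effects) {
  const int np = v_base.size();
  const int ns = 25;
  if (state0.size() != ns) stop("state0 must have 25 stocks");
  NumericMatrix states(n_steps + 1, ns);
  NumericMatrix aux(n_steps + 1, 3);
  std::vector<double> s(ns), r(ns), v(np), a(3);
  const double* v0 = REAL(v_base);
  for (int i = 0; i < ns; ++i) s[i] = state0[i];

  effective_params(v0, v.data(), np, effects, t0);
  core_aux(s.data(), v.data(), a.data());
  for (int i = 0; i < ns; ++i) states(0, i) = s[i];
  for (int i = 0; i < 3; ++i) aux(0, i) = a[i];

  int n_clamped = 0;
  for (int k = 0; k < n_steps; ++k) {
    double t = t0 + k * dt;
    effective_params(v0, v.data(), np, effects, t);
    core_rates(s.data(), v.data(), r.data());
    for (int i = 0; i < ns; ++i) {
      if (!R_finite(r[i])) stop("non-finite flow rate at step %d", k + 1);
      s[i] += dt * r[i];
      if (s[i] < 0.0) { s[i] = 0.0; ++n_clamped; }
    }
    double tnext = t0 + (k + 1) * dt;
    effective_params(v0, v.data(), np, effects, tnext);
    core_aux(s.data(), v.data(), a.data());
    for (int i = 0; i < ns; ++i) states(k + 1, i) = s[i];
    for (int i = 0; i < 3; ++i) aux(k + 1, i) = a[i];
  }
  return List::create(_["states"] = states, _["aux"] = aux,
                      _["n_clamped"] = n_clamped);
}
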