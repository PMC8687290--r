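#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the coupled regulation system
//   dx/dt = f(x, V)            (floored below x_floor by a C1 taper)
//   dV/dt = -W^-1 grad_V psi   (clamped below V_min by a C1 taper)
// evaluated over the flattened occurrence arrays of the rate-law engine.
// Mirrors the R reference implementation (engine_u / engine_dudV /
// grad_psi_parameters); tests assert the two paths agree.

static inline double smoothstep(double z) {
  if (z <= 0.0) return 0.0;
  if (z >= 1.0) return 1.0;
  return z * z * (3.0 - 2.0 * z);
}

// [[Rcpp::export(name = ".coupled_rhs_cpp")]]
NumericVector coupled_rhs_cpp(NumericVector state, List ctx) {
  const NumericMatrix S = ctx["S"];            // n_met x n_rxn kinetic block
  const IntegerVector sub_r = ctx["sub_r"];    // 1-based reaction index
  const IntegerVector sub_m = ctx["sub_m"];    // 1-based metabolite, 0 = external
  const NumericVector Ks = ctx["Ks"];
  const IntegerVector prod_r = ctx["prod_r"];
  const IntegerVector prod_m = ctx["prod_m"];
  const NumericVector Kp = ctx["Kp"];
  const NumericVector VF0 = ctx["VF"];
  const NumericVector VB0 = ctx["VB"];
  const IntegerVector idxF = ctx["idxF"];      // 1-based reaction index per VF state
  const IntegerVector idxB = ctx["idxB"];
  const NumericVector const_term = ctx["const_term"];
  const NumericVector Dinv = ctx["Dinv"];
  const NumericVector Winv = ctx["Winv"];      // length nv
  const double x_floor = as<double>(ctx["x_floor"]);
  const double v_min = as<double>(ctx["v_min"]);
  const double clamp_width = as<double>(ctx["clamp_width"]);
  const bool swapped = as<bool>(ctx["swapped"]);

  const int n_met = S.nrow();
  const int n_rxn = S.ncol();
  const int nF = idxF.size();
  const int nB = idxB.size();
  const int nv = nF + nB;

  std::vector<double> x(n_met), VF(VF0.begin(), VF0.end()),
      VB(VB0.begin(), VB0.end());
  for (int i = 0; i < n_met; ++i)
    x[i] = std::max(state[i], x_floor);
  for (int k = 0; k < nF; ++k)
    VF[idxF[k] - 1] = std::max(state[n_met + k], v_min);
  for (int k = 0; k < nB; ++k)
    VB[idxB[k] - 1] = std::max(state[n_met + nF + k], v_min);

  // group products over occurrences
  std::vector<double> a(n_rxn, 1.0), p(n_rxn, 1.0), SA(n_rxn, 1.0),
      SP(n_rxn, 1.0);
  for (int t = 0; t < sub_r.size(); ++t) {
    const int r = sub_r[t] - 1;
    const double conc = (sub_m[t] == 0) ? 1.0 : x[sub_m[t] - 1];
    const double z = conc / Ks[t];
    a[r] *= z;
    SA[r] *= 1.0 + z;
  }
  for (int t = 0; t < prod_r.size(); ++t) {
    const int r = prod_r[t] - 1;
    const double conc = (prod_m[t] == 0) ? 1.0 : x[prod_m[t] - 1];
    const double z = conc / Kp[t];
    p[r] *= z;
    SP[r] *= 1.0 + z;
  }
  if (swapped) std::swap(SA, SP);

  std::vector<double> u(n_rxn), duF(n_rxn), duB(n_rxn);
  for (int r = 0; r < n_rxn; ++r) {
    const double tot = VF[r] + VB[r];
    const double den = (VF[r] * SA[r] + VB[r] * SP[r]) / tot;
    const double num = VF[r] * a[r] - VB[r] * p[r];
    u[r] = num / den;
    const double ddenF = (VB[r] / (tot * tot)) * (SA[r] - SP[r]);
    const double ddenB = (VF[r] / (tot * tot)) * (SP[r] - SA[r]);
    duF[r] = (a[r] * den - num * ddenF) / (den * den);
    duB[r] = (-p[r] * den - num * ddenB) / (den * den);
  }

  NumericVector out(n_met + nv);
  std::vector<double> f(n_met, 0.0);
  for (int r = 0; r < n_rxn; ++r) {
    const double ur = u[r];
    for (int i = 0; i < n_met; ++i) f[i] += S(i, r) * ur;
  }
  for (int i = 0; i < n_met; ++i) f[i] += const_term[i];

  // c_r = sum_m S[m,r] * f_m / D_m
  std::vector<double> cvec(n_rxn, 0.0);
  for (int r = 0; r < n_rxn; ++r) {
    double acc = 0.0;
    for (int i = 0; i < n_met; ++i) acc += S(i, r) * f[i] * Dinv[i];
    cvec[r] = acc;
  }

  for (int i = 0; i < n_met; ++i) {
    double dx = f[i];
    if (dx < 0.0)
      dx *= smoothstep((state[i] - x_floor) / x_floor);
    out[i] = dx;
  }
  for (int k = 0; k < nv; ++k) {
    const int r = (k < nF) ? idxF[k] - 1 : idxB[k - nF] - 1;
    const double du = (k < nF) ? duF[r] : duB[r];
    double dV = -Winv[k] * 2.0 * cvec[r] * du;
    if (dV < 0.0)
      dV *= smoothstep((state[n_met + k] - v_min) / clamp_width);
    out[n_met + k] = dV;
  }
  return out;
}

// x-only right-hand side at fixed velocities (same floor taper); used by the
// quasi-static regulation mode for fast metabolite relaxation.
// [[Rcpp::export(name = ".x_rhs_cpp")]]
NumericVector x_rhs_cpp(NumericVector state, List ctx, NumericVector VF,
                        NumericVector VB) {
  const NumericMatrix S = ctx["S"];
  const IntegerVector sub_r = ctx["sub_r"];
  const IntegerVector sub_m = ctx["sub_m"];
  const NumericVector Ks = ctx["Ks"];
  const IntegerVector prod_r = ctx["prod_r"];
  const IntegerVector prod_m = ctx["prod_m"];
  const NumericVector Kp = ctx["Kp"];
  const NumericVector const_term = ctx["const_term"];
  const double x_floor = as<double>(ctx["x_floor"]);
  const bool swapped = as<bool>(ctx["swapped"]);

  const int n_met = S.nrow();
  const int n_rxn = S.ncol();
  std::vector<double> x(n_met);
  for (int i = 0; i < n_met; ++i) x[i] = std::max(state[i], x_floor);

  std::vector<double> a(n_rxn, 1.0), p(n_rxn, 1.0), SA(n_rxn, 1.0),
      SP(n_rxn, 1.0);
  for (int t = 0; t < sub_r.size(); ++t) {
    const int r = sub_r[t] - 1;
    const double conc = (sub_m[t] == 0) ? 1.0 : x[sub_m[t] - 1];
    const double z = conc / Ks[t];
    a[r] *= z;
    SA[r] *= 1.0 + z;
  }
  for (int t = 0; t < prod_r.size(); ++t) {
    const int r = prod_r[t] - 1;
    const double conc = (prod_m[t] == 0) ? 1.0 : x[prod_m[t] - 1];
    const double z = conc / Kp[t];
    p[r] *= z;
    SP[r] *= 1.0 + z;
  }
  if (swapped) std::swap(SA, SP);

  NumericVector out(n_met);
  std::vector<double> f(n_met, 0.0);
  for (int r = 0; r < n_rxn; ++r) {
    const double tot = VF[r] + VB[r];
    const double den = (VF[r] * SA[r] + VB[r] * SP[r]) / tot;
    const double u = (VF[r] * a[r] - VB[r] * p[r]) / den;
    for (int i = 0; i < n_met; ++i) f[i] += S(i, r) * u;
  }
  for (int i = 0; i < n_met; ++i) {
    double dx = f[i] + const_term[i];
    if (dx < 0.0)
      dx *= smoothstep((state[i] - x_floor) / x_floor);
    out[i] = dx;
  }
  return out;
}
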