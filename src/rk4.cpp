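#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step classical RK4 integrator for the mass-action network.
// Serves as the brute-force reference against which the adaptive solver is
// checked; kept deliberately simple (no step control, no interpolation:
// output times are snapped to the fixed grid by the caller).
//
// km:    per-reaction rate constant x statistical multiplicity
// r1,r2: 1-based reactant indices; r2 = 0 for unimolecular reactions
// si,sj,sv: stoichiometry triplets (species index, reaction index, coef)
// clampIdx: 1-based index of the clamped species (free ligand)

static inline void rhs(const std::vector<double>& y, std::vector<double>& dy,
                       const NumericVector& km, const IntegerVector& r1,
                       const IntegerVector& r2, const IntegerVector& si,
                       const IntegerVector& sj, const NumericVector& sv,
                       std::vector<double>& rates, int clampIdx) {
  const int nr = km.size();
  for (int j = 0; j < nr; ++j) {
    double v = km[j] * y[r1[j] - 1];
    if (r2[j] > 0) v *= y[r2[j] - 1];
    rates[j] = v;
  }
  std::fill(dy.begin(), dy.end(), 0.0);
  const int nnz = si.size();
  for (int t = 0; t < nnz; ++t)
    dy[si[t] - 1] += sv[t] * rates[sj[t] - 1];
  dy[clampIdx - 1] = 0.0;
}

// [[Rcpp::export(name = ".rk4_integrate")]]
NumericMatrix rk4_integrate(NumericVector y0, NumericVector outTimes,
                            double dt, NumericVector km, IntegerVector r1,
                            IntegerVector r2, IntegerVector si,
                            IntegerVector sj, NumericVector sv,
                            int clampIdx) {
  const int n = y0.size();
  const int nout = outTimes.size();
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  std::vector<double> rates(km.size());
  NumericMatrix out(nout, n);

  int iout = 0;
  double t = 0.0;
  // record any output times at (or numerically before) t = 0
  while (iout < nout && outTimes[iout] <= 1e-12) {
    for (int i = 0; i < n; ++i) out(iout, i) = y[i];
    ++iout;
  }
  if (iout >= nout) return out;

  const double tEnd = outTimes[nout - 1];
  const long nsteps = (long)std::ceil(tEnd / dt - 1e-9);
  for (long s = 0; s < nsteps; ++s) {
    rhs(y, k1, km, r1, r2, si, sj, sv, rates, clampIdx);
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    rhs(tmp, k2, km, r1, r2, si, sj, sv, rates, clampIdx);
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    rhs(tmp, k3, km, r1, r2, si, sj, sv, rates, clampIdx);
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + dt * k3[i];
    rhs(tmp, k4, km, r1, r2, si, sj, sv, rates, clampIdx);
    for (int i = 0; i < n; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t = (s + 1) * dt;
    while (iout < nout && outTimes[iout] <= t + 1e-9 * std::max(1.0, t)) {
      for (int i = 0; i < n; ++i) out(iout, i) = y[i];
      ++iout;
    }
    if (iout >= nout) break;
  }
  return out;
}
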