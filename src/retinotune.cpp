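#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler integration of a passive compartmental cable.
// Units: capacitance nF, conductance uS, time ms, voltage mV
// (nF/ms == uS, so C dV/dt and g(V - E) are commensurate).
// Synaptic conductances gE, gI (one value per time step) act on
// compartment syn_idx (1-based). The chain is soma = compartment 1,
// dendrite = compartments 2..n, coupled by ga[i] between i and i+1.
// Returns the membrane potential of compartment record_idx at every
// record_every-th step.
// [[Rcpp::export]]
NumericVector simulate_cable_cpp(NumericVector cap_nF,
                                 NumericVector gleak_uS,
                                 double e_leak,
                                 NumericVector ga_uS,
                                 int syn_idx,
                                 NumericVector gE_uS,
                                 NumericVector gI_uS,
                                 double e_exc, double e_inh,
                                 double dt_ms,
                                 int record_every,
                                 int record_idx) {
  const int nc = cap_nF.size();
  const int nt = gE_uS.size();
  if (gI_uS.size() != nt) stop("gE and gI must have equal length");
  if (syn_idx < 1 || syn_idx > nc) stop("syn_idx out of range");
  if (record_idx < 1 || record_idx > nc) stop("record_idx out of range");
  if (ga_uS.size() != nc - 1) stop("need one axial conductance per pair");

  std::vector<double> V(nc, e_leak);
  std::vector<double> a(nc), b(nc), c(nc), d(nc), cp(nc), dp(nc);
  const int nrec = nt / record_every;
  NumericVector out(nrec);
  int k = 0;

  for (int t = 0; t < nt; ++t) {
    // assemble tridiagonal system (C/dt + G) V_new = C/dt V + rhs
    for (int i = 0; i < nc; ++i) {
      double diag = cap_nF[i] / dt_ms + gleak_uS[i];
      double rhs = cap_nF[i] / dt_ms * V[i] + gleak_uS[i] * e_leak;
      if (i > 0) diag += ga_uS[i - 1];
      if (i < nc - 1) diag += ga_uS[i];
      if (i == syn_idx - 1) {
        diag += gE_uS[t] + gI_uS[t];
        rhs += gE_uS[t] * e_exc + gI_uS[t] * e_inh;
      }
      b[i] = diag;
      d[i] = rhs;
      a[i] = (i > 0) ? -ga_uS[i - 1] : 0.0;
      c[i] = (i < nc - 1) ? -ga_uS[i] : 0.0;
    }
    // Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int i = 1; i < nc; ++i) {
      double m = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / m;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / m;
    }
    V[nc - 1] = dp[nc - 1];
    for (int i = nc - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];

    if ((t + 1) % record_every == 0 && k < nrec) {
      out[k++] = V[record_idx - 1];
    }
  }
  if (!std::isfinite(out[nrec - 1]))
    stop("membrane integration became non-finite; reduce dt");
  return out;
}

// Normalized least-mean-squares adaptive FIR identification.
// w <- w + mu * e * x / (eps + ||x||^2), run n_passes times over the
// record. Returns the converged kernel and the mean squared error of
// each pass (for divergence checks).
// [[Rcpp::export]]
List nlms_cpp(NumericVector x, NumericVector d, int L, double mu,
              double eps, int n_passes) {
  const int n = x.size();
  if (d.size() != n) stop("input and output must have equal length");
  if (L < 1 || L > n) stop("invalid filter length");
  std::vector<double> w(L, 0.0);
  NumericVector mse(n_passes);

  for (int p = 0; p < n_passes; ++p) {
    double se = 0.0;
    int cnt = 0;
    for (int t = L - 1; t < n; ++t) {
      double yhat = 0.0, nrm = eps;
      for (int k = 0; k < L; ++k) {
        const double xv = x[t - k];
        yhat += w[k] * xv;
        nrm += xv * xv;
      }
      const double e = d[t] - yhat;
      const double g = mu * e / nrm;
      for (int k = 0; k < L; ++k) w[k] += g * x[t - k];
      se += e * e;
      ++cnt;
    }
    mse[p] = se / cnt;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["mse"] = mse);
}
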