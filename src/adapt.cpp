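#include <Rcpp.h>
using namespace Rcpp;

// Per-channel trial recursion of the adaptation stage.  For each trial t:
//   ASYN_t = max(SYN_t - A_t, 0)             (clamped at zero)
//   A_{t+1} = (1 - R) * (A_t + g(ASYN_t)),   g(x) = [m + (M-m) 2^(-x/tau)] x
// A starts at `A0` (zeros for a fresh sequence).
// [[Rcpp::export]]
List adapt_recursion_cpp(NumericMatrix syn, double M, double m, double tau,
                         double R, NumericVector A0) {
  const int nt = syn.nrow(), nk = syn.ncol();
  NumericMatrix asyn(nt, nk);
  NumericVector in_total(nt);
  NumericVector A = clone(A0);
  for (int t = 0; t < nt; ++t) {
    double s = 0.0;
    for (int k = 0; k < nk; ++k) {
      double a = syn(t, k) - A[k];
      if (a < 0.0) a = 0.0;
      asyn(t, k) = a;
      s += a;
      double alpha = m + (M - m) * std::pow(2.0, -a / tau);
      A[k] = (1.0 - R) * (A[k] + alpha * a);
    }
    in_total[t] = s;
  }
  return List::create(_["asyn"] = asyn, _["in_total"] = in_total,
                      _["A_final"] = A);
}

// Same recursion but returning only the integrated adapted input per trial;
// avoids allocating the per-channel trace inside optimizer loops.
// [[Rcpp::export]]
NumericVector adapt_in_total_cpp(NumericMatrix syn, double M, double m,
                                 double tau, double R) {
  const int nt = syn.nrow(), nk = syn.ncol();
  NumericVector in_total(nt);
  const double oneR = 1.0 - R;
  const double lg = M_LN2 / tau;
  // channels never driven keep A = 0 and contribute nothing; skip them
  std::vector<int> active;
  active.reserve(nk);
  for (int k = 0; k < nk; ++k) {
    bool any = false;
    for (int t = 0; t < nt; ++t)
      if (syn(t, k) != 0.0) { any = true; break; }
    if (any) active.push_back(k);
  }
  std::vector<double> A(active.size(), 0.0);
  for (int t = 0; t < nt; ++t) {
    double s = 0.0;
    for (size_t j = 0; j < active.size(); ++j) {
      double a = syn(t, active[j]) - A[j];
      if (a < 0.0) a = 0.0;
      s += a;
      double alpha = m + (M - m) * std::exp(-lg * a);
      A[j] = oneR * (A[j] + alpha * a);
    }
    in_total[t] = s;
  }
  return in_total;
}
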