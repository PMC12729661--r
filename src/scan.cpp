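// Selective-scan recurrence kernels - the hot path of the state-space
// encoder. This translation unit is compiled with fast-math (see Makevars)
// so the per-step exponentials, hoisted into one long contiguous loop per
// time step, map onto the vectorized math library.
//
//   h_t = exp(delta_t * A) . h_{t-1} + delta_t * B_t * u_t
//   y_t = sum_n C_t[n] h_t[., n] + D . u_t
//
// u, delta: d x L;  A: d x N;  B, Cc: N x L;  D: d.
// The state history is stored N-major: hist[(n + N*i), t].

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_scan_fwd")]]
List cpp_scan_fwd(NumericMatrix u, NumericMatrix delta,
                  NumericMatrix A, NumericMatrix B,
                  NumericMatrix Cc, NumericVector D) {
  const int d = u.nrow(), L = u.ncol(), N = A.ncol();
  NumericMatrix y(d, L), hist(d * N, L);
  const int Nd = N * d;
  std::vector<double> At(Nd);            // A transposed: contiguous over n
  for (int i = 0; i < d; ++i)
    for (int n = 0; n < N; ++n) At[N * i + n] = A(i, n);
  std::vector<double> h(Nd, 0.0), e(Nd);
  double* ep = e.data();
  const double* Ap = At.data();
  double* yp = y.begin();
  double* histp = hist.begin();
  const double* up = u.begin();
  const double* dp = delta.begin();
  const double* Bp = B.begin();
  const double* Cp = Cc.begin();
  const double* Dp = D.begin();
  for (int t = 0; t < L; ++t) {
    const double* dt_col = dp + (size_t)d * t;
    const double* u_col = up + (size_t)d * t;
    const double* Bt = Bp + (size_t)N * t;
    const double* Ct = Cp + (size_t)N * t;
    double* ht_out = histp + (size_t)Nd * t;
    for (int i = 0; i < d; ++i) {
      const double dt = dt_col[i];
      for (int n = 0; n < N; ++n) ep[N * i + n] = dt * Ap[N * i + n];
    }
    for (int j = 0; j < Nd; ++j) ep[j] = std::exp(ep[j]);
    for (int i = 0; i < d; ++i) {
      const double dtu = dt_col[i] * u_col[i];
      double* hi = h.data() + (size_t)N * i;
      const double* ei = ep + (size_t)N * i;
      double acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double hn = ei[n] * hi[n] + dtu * Bt[n];
        hi[n] = hn;
        acc += Ct[n] * hn;
      }
      yp[i + (size_t)d * t] = acc + Dp[i] * u_col[i];
    }
    std::copy(h.begin(), h.end(), ht_out);
  }
  return List::create(_["y"] = y, _["h"] = hist);
}

// [[Rcpp::export(name = ".cpp_scan_bwd")]]
List cpp_scan_bwd(NumericMatrix u, NumericMatrix delta,
                  NumericMatrix A, NumericMatrix B,
                  NumericMatrix Cc, NumericVector D,
                  NumericMatrix hist, NumericMatrix gy) {
  const int d = u.nrow(), L = u.ncol(), N = A.ncol();
  NumericMatrix gu(d, L), gdelta(d, L), gB(N, L), gC(N, L);
  NumericMatrix gA(d, N);
  NumericVector gD(d);
  const int Nd = N * d;
  std::vector<double> At(Nd), gAtv(Nd, 0.0);
  for (int i = 0; i < d; ++i)
    for (int n = 0; n < N; ++n) At[N * i + n] = A(i, n);
  std::vector<double> dh(Nd, 0.0), e(Nd);
  double* ep = e.data();
  const double* Ap = At.data();
  const double* up = u.begin();
  const double* dp = delta.begin();
  const double* Bp = B.begin();
  const double* Cp = Cc.begin();
  const double* Dp = D.begin();
  const double* histp = hist.begin();
  const double* gyp = gy.begin();
  for (int t = L - 1; t >= 0; --t) {
    const double* dt_col = dp + (size_t)d * t;
    const double* u_col = up + (size_t)d * t;
    const double* Bt = Bp + (size_t)N * t;
    const double* Ct = Cp + (size_t)N * t;
    const double* ht = histp + (size_t)Nd * t;
    const double* htm = (t > 0) ? ht - Nd : nullptr;
    double* gBt = gB.begin() + (size_t)N * t;
    double* gCt = gC.begin() + (size_t)N * t;
    for (int i = 0; i < d; ++i) {
      const double dt = dt_col[i];
      for (int n = 0; n < N; ++n) ep[N * i + n] = dt * Ap[N * i + n];
    }
    for (int j = 0; j < Nd; ++j) ep[j] = std::exp(ep[j]);
    for (int i = 0; i < d; ++i) {
      const double g = gyp[i + (size_t)d * t];
      const double dt = dt_col[i], ut = u_col[i];
      gD[i] += g * ut;
      const double* Ai = Ap + (size_t)N * i;
      double* gAi = gAtv.data() + (size_t)N * i;
      double* dhi = dh.data() + (size_t)N * i;
      const double* hti = ht + (size_t)N * i;
      const double* ei = ep + (size_t)N * i;
      double gu_acc = g * Dp[i], gdt_acc = 0.0;
      for (int n = 0; n < N; ++n) {
        gCt[n] += g * hti[n];
        const double dhn = dhi[n] + g * Ct[n];
        const double hprev = htm ? htm[(size_t)N * i + n] : 0.0;
        const double dabar_abar = dhn * hprev * ei[n];
        gdt_acc += dabar_abar * Ai[n] + dhn * Bt[n] * ut;
        gAi[n] += dabar_abar * dt;
        gBt[n] += dhn * dt * ut;
        gu_acc += dhn * dt * Bt[n];
        dhi[n] = dhn * ei[n];
      }
      gu(i, t) = gu_acc;
      gdelta(i, t) = gdt_acc;
    }
  }
  for (int i = 0; i < d; ++i)
    for (int n = 0; n < N; ++n) gA(i, n) = gAtv[N * i + n];
  return List::create(_["gu"] = gu, _["gdelta"] = gdelta, _["gA"] = gA,
                      _["gB"] = gB, _["gC"] = gC, _["gD"] = gD);
}
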