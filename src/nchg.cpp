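#include <Rcpp.h>
using namespace Rcpp;

// Fisher noncentral hypergeometric upper-tail survival probabilities.
//
// Null for one bin pair: population 2n, n_i success states, n_j draws, odds
// ratio omega. Unnormalized log-weight of k co-occurring contacts is
// lchoose(n_i, k) + lchoose(2n - n_i, n_j - k) + k log(omega); the pmf is the
// weight normalized over the support [max(0, n_j - (2n - n_i)), min(n_i, n_j)].
// Weights are built by a log-space recurrence from the support minimum and
// normalized with log-sum-exp, so the tail is exact to double precision even
// when n is in the millions.
// [[Rcpp::export(name = ".nchg_tail_cpp")]]
NumericVector nchg_tail_cpp(NumericVector k, NumericVector n,
                            NumericVector ni, NumericVector nj,
                            NumericVector omega) {
  const R_xlen_t m = k.size();
  NumericVector out(m);
  std::vector<double> lw;
  for (R_xlen_t idx = 0; idx < m; ++idx) {
    const double N2 = 2.0 * n[idx];
    const double a = ni[idx], b = nj[idx], w = omega[idx];
    if (!(w > 0) || a < 0 || b < 0 || a > N2 || b > N2 || n[idx] <= 0)
      stop("invalid NCHG parameters (need omega > 0, 0 <= n_i, n_j <= 2n)");
    const double kmin = std::max(0.0, b - (N2 - a));
    const double kmax = std::min(a, b);
    const double nstates = kmax - kmin + 1.0;
    if (nstates > 1e6)
      stop("NCHG support exceeds 1e6 states; refusing to enumerate");
    const double kk = k[idx];
    if (kk <= kmin) { out[idx] = 1.0; continue; }
    if (kk > kmax) { out[idx] = 0.0; continue; }
    const int S = (int) nstates;
    lw.assign(S, 0.0);
    const double logw = std::log(w);
    lw[0] = R::lchoose(a, kmin) + R::lchoose(N2 - a, b - kmin) + kmin * logw;
    for (int s = 1; s < S; ++s) {
      const double kp = kmin + s - 1;  // previous k
      lw[s] = lw[s - 1] + std::log(a - kp) - std::log(kp + 1.0)
            + std::log(b - kp) - std::log(N2 - a - b + kp + 1.0) + logw;
    }
    const double mx = *std::max_element(lw.begin(), lw.end());
    double denom = 0.0, tail = 0.0;
    const int kidx = (int) std::ceil(kk - kmin);  // first state with k' >= k
    for (int s = 0; s < S; ++s) {
      const double e = std::exp(lw[s] - mx);
      denom += e;
      if (s >= kidx) tail += e;
    }
    // discrete survival probabilities are strictly positive on the support;
    // keep underflowed tails at the smallest normal double
    out[idx] = std::min(1.0, std::max(tail / denom, DBL_MIN));
  }
  return out;
}
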