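// Compiled cores: eigenbasis propagation of the photon-by-photon likelihood
// and the Gillespie realization of the composite jump process.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Photon-by-photon log-likelihood in the eigenbasis of the nonradiative
// generator H = V diag(d) V^{-1}. The propagated row vector is kept in
// eigen coordinates u = rho %*% V; each interphoton interval is an
// elementwise multiply by exp(d * tau), each detection a multiply by
// B[c] = V^{-1} D_c V. Per-step L1 renormalization with accumulated log
// scale factors prevents underflow for arbitrarily long traces.
//
// u0       : rho_start %*% V (complex row vector)
// d        : eigenvalues of H
// B1, B2   : per-channel detection matrices conjugated into the eigenbasis
// channels : channel label per photon (1 or 2)
// taus     : K + 1 interval lengths (pre-photon gaps then terminal gap)
// vinv_one : V^{-1} %*% ones (sums the terminal distribution)
// [[Rcpp::export]]
double loglik_eigen_core(const arma::cx_rowvec& u0,
                         const arma::cx_vec& d,
                         const arma::cx_mat& B1,
                         const arma::cx_mat& B2,
                         const arma::ivec& channels,
                         const arma::vec& taus,
                         const arma::cx_vec& vinv_one) {
  const arma::uword K = channels.n_elem;
  if (taus.n_elem != K + 1) stop("taus must have length K + 1");
  const arma::uword n = d.n_elem;
  const arma::vec re_d = arma::real(d);
  arma::cx_rowvec u = u0;
  arma::cx_rowvec w(n), nxt(n);
  std::vector<arma::uword> alive;
  alive.reserve(n);
  double logscale = 0.0;
  for (arma::uword k = 0; k <= K; ++k) {
    const double tau = taus(k);
    // modes whose interval exponential underflows to exactly zero are
    // skipped; identical to the dense product in double precision
    alive.clear();
    for (arma::uword i = 0; i < n; ++i) {
      if (re_d(i) * tau > -746.0) {
        w(i) = u(i) * std::exp(d(i) * tau);
        alive.push_back(i);
      } else {
        w(i) = arma::cx_double(0.0, 0.0);
      }
    }
    if (k == K) break;
    const arma::cx_mat& B = (channels(k) == 1) ? B1 : B2;
    nxt.zeros();
    for (arma::uword j = 0; j < n; ++j) {
      arma::cx_double acc(0.0, 0.0);
      for (arma::uword ii = 0; ii < alive.size(); ++ii) {
        const arma::uword i = alive[ii];
        acc += w(i) * B(i, j);
      }
      nxt(j) = acc;
    }
    u = nxt;
    double s = arma::accu(arma::abs(u));
    if (!std::isfinite(s) || s <= 0.0) {
      stop("non-finite likelihood propagation at photon %d", (int)(k + 1));
    }
    u /= s;
    logscale += std::log(s);
  }
  double val = std::real(arma::as_scalar(w * vinv_one));
  if (!std::isfinite(val)) stop("non-finite terminal likelihood value");
  if (val <= 0.0) return R_NegInf;
  return logscale + std::log(val);
}

// Exact Gillespie realization of the jump process with generator Ga over
// active superstates. psi gives each state's photophysical index (1..3);
// a jump with psi 2 -> 1 logs a donor emission, psi 3 -> 1 an acceptor
// emission. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List gillespie_core(const arma::mat& Ga,
                    const arma::ivec& psi,
                    int start_state,
                    double t_start,
                    double t_end,
                    bool keep_jumps) {
  const int n = Ga.n_rows;
  if (start_state < 1 || start_state > n) stop("invalid start state");
  std::vector<double> em_t, jump_t;
  std::vector<int> em_dye, jump_state;
  em_t.reserve(1024);
  em_dye.reserve(1024);
  int s = start_state - 1;
  double t = t_start;
  while (true) {
    double total = -Ga(s, s);
    if (total <= 0.0) {
      if (n > 1) stop("absorbing superstate %d encountered", s + 1);
      break;  // single zero-rate state: sits still until t_end
    }
    t += -std::log(unif_rand()) / total;
    if (t >= t_end) break;
    // categorical draw over off-diagonal row entries
    double u = unif_rand() * total, acc = 0.0;
    int nxt = -1;
    for (int j = 0; j < n; ++j) {
      if (j == s) continue;
      acc += Ga(s, j);
      if (u <= acc) { nxt = j; break; }
    }
    if (nxt < 0) {  // numerical slack: take last positive-rate target
      for (int j = n - 1; j >= 0; --j) {
        if (j != s && Ga(s, j) > 0.0) { nxt = j; break; }
      }
      if (nxt < 0) stop("no admissible jump target from state %d", s + 1);
    }
    if (psi(s) == 2 && psi(nxt) == 1) {
      em_t.push_back(t); em_dye.push_back(1);   // donor photon
    } else if (psi(s) == 3 && psi(nxt) == 1) {
      em_t.push_back(t); em_dye.push_back(2);   // acceptor photon
    }
    if (keep_jumps) { jump_t.push_back(t); jump_state.push_back(nxt + 1); }
    s = nxt;
  }
  List out = List::create(
    Named("em_time") = em_t,
    Named("em_dye") = em_dye,
    Named("final_state") = s + 1);
  if (keep_jumps) {
    out["jump_time"] = jump_t;
    out["jump_state"] = jump_state;
  }
  return out;
}
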