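#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Rectified sigmoid: 0 for x <= 0, tanh(gain * x) for x > 0.
// Must stay in lockstep with squash() on the R side.
static inline void squash_inplace(arma::vec& x, double gain) {
  for (arma::uword i = 0; i < x.n_elem; ++i)
    x[i] = x[i] > 0.0 ? std::tanh(gain * x[i]) : 0.0;
}

// Square-pulse input: channel values (c1, c2) while t lies inside any
// [onset, offset) interval, zero otherwise.  Pulses are few, linear scan.
static inline void input_at(double t, const arma::vec& onsets,
                            const arma::vec& offsets, double c1, double c2,
                            arma::vec& g) {
  g[0] = 0.0;
  g[1] = 0.0;
  for (arma::uword p = 0; p < onsets.n_elem; ++p) {
    if (t >= onsets[p] && t < offsets[p]) {
      g[0] = c1;
      g[1] = c2;
      return;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".sim_rk4_core")]]
arma::mat sim_rk4_core(const arma::mat& W, const arma::mat& A,
                       const arma::vec& tau, const arma::vec& onsets,
                       const arma::vec& offsets, double c1, double c2,
                       double duration, double dt, const arma::vec& init,
                       const arma::mat& noise, double gain) {
  const arma::uword n = W.n_rows;
  const arma::uword nsteps = (arma::uword)std::llround(duration / dt);
  const bool use_noise = noise.n_cols > 0;

  arma::mat out(n, nsteps + 1);
  arma::vec a = init, g(2), k1(n), k2(n), k3(n), k4(n), tmp(n);
  out.col(0) = a;

  for (arma::uword s = 0; s < nsteps; ++s) {
    const double t = s * dt;

    // tau * da/dt = -a + f(W a + A g(t)).  g is held at its value at the
    // left endpoint of the step: pulse edges lie on the ms grid, so every
    // step then sits inside one constant-input piece and the integration is
    // exact piecewise (no stage ever straddles a stimulus discontinuity).
    input_at(t, onsets, offsets, c1, c2, g);
    k1 = W * a + A * g;
    squash_inplace(k1, gain);
    k1 = (k1 - a) / tau;

    tmp = a + 0.5 * dt * k1;
    k2 = W * tmp + A * g;
    squash_inplace(k2, gain);
    k2 = (k2 - tmp) / tau;

    tmp = a + 0.5 * dt * k2;
    k3 = W * tmp + A * g;
    squash_inplace(k3, gain);
    k3 = (k3 - tmp) / tau;

    tmp = a + dt * k3;
    k4 = W * tmp + A * g;
    squash_inplace(k4, gain);
    k4 = (k4 - tmp) / tau;

    a += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (use_noise) a += noise.col(s);
    a = arma::clamp(a, 0.0, 1.0);
    out.col(s + 1) = a;
  }
  return out;
}
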