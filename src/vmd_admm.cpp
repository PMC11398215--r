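// ADMM iteration of variational mode decomposition over the (fftshifted)
// frequency grid. Only the non-negative half-plane is updated; synthesis and
// Hermitian completion happen on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// f_hat_plus : fftshifted spectrum of the (possibly mirrored) signal with
//              negative-frequency bins zeroed, length T
// freqs      : fftshifted frequency grid in cycles/sample, in [-0.5, 0.5)
// omega_init : K initial center frequencies (cycles/sample)
// alpha      : bandwidth penalty; tau: dual ascent step; tol: Eq.-style
//              relative-change stopping threshold; max_iter: iteration cap
// [[Rcpp::export(name = ".vmd_admm")]]
Rcpp::List vmd_admm(const arma::cx_vec& f_hat_plus,
                    const arma::vec& freqs,
                    const arma::vec& omega_init,
                    double alpha, double tau, double tol, int max_iter) {
  const uword T = f_hat_plus.n_elem;
  const int K = omega_init.n_elem;
  const uvec pos = find(freqs >= 0.0);          // non-negative bins
  const vec fpos = freqs.elem(pos);

  cx_mat u_hat(T, K, fill::zeros);
  cx_mat u_prev(T, K, fill::zeros);
  cx_vec lambda_hat(T, fill::zeros);
  vec omega = omega_init;

  double udiff = tol + 1.0;
  double residual = NA_REAL;
  std::vector<double> history;
  int n = 0;
  const double tiny = 1e-300;

  while (udiff > tol && n < max_iter) {
    for (int k = 0; k < K; ++k) {
      cx_vec sum_others(T, fill::zeros);
      for (int j = 0; j < K; ++j)
        if (j != k) sum_others += u_hat.col(j);
      // Wiener-filter mode update on the half plane
      vec denom = 1.0 + 2.0 * alpha * square(freqs - omega(k));
      u_hat.col(k) = (f_hat_plus - sum_others + lambda_hat / 2.0) / denom;
      // power-weighted mean frequency (spectral centroid over omega >= 0)
      vec amp = abs(cx_vec(u_hat.col(k)));
      vec p = square(amp.elem(pos));
      double den = accu(p);
      if (den > tiny) omega(k) = dot(fpos, p) / den;
      // zero-energy mode: keep previous omega
    }
    cx_vec usum(T, fill::zeros);
    for (int k = 0; k < K; ++k) usum += u_hat.col(k);
    lambda_hat += tau * (f_hat_plus - usum);
    ++n;
    udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      double num = accu(square(abs(u_hat.col(k) - u_prev.col(k))));
      double den = accu(square(abs(u_prev.col(k))));
      udiff += num / std::max(den, tiny);
    }
    residual = udiff;
    history.push_back(udiff);
    u_prev = u_hat;
  }

  return Rcpp::List::create(
    Rcpp::Named("u_hat") = u_hat,
    Rcpp::Named("omega") = omega,
    Rcpp::Named("lambda_hat") = lambda_hat,
    Rcpp::Named("n_iter") = n,
    Rcpp::Named("converged") = (udiff <= tol),
    Rcpp::Named("residual") = residual,
    Rcpp::Named("residual_history") = history);
}
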