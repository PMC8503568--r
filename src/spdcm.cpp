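// Numerical kernels for spectral-DCM prediction, its finite-difference
// Jacobian, and stochastic simulation of the latent linear dynamics.
// Parameter layout (must match pack_params()/unpack_params() in R):
//   [ a_offdiag (column-major over allowed off-diagonal mask entries),
//     self_log (R), log_alpha_v, b_v, log_alpha_e, b_e,
//     decay_log (R), transit_log (R) ]
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SELF_RATE = 0.5;   // -0.5*exp(s) Hz self-inhibition
static const double KAPPA0 = 0.64;     // 1/s, signal-decay pole scale
static const double GAMMA0 = 0.32;     // 1/s, transit pole scale

// logistic map of an unconstrained real onto (0, 2): power-law exponents
static double beta_map(double b) { return 2.0 / (1.0 + std::exp(-b)); }

static mat assemble_A_cpp(const vec& theta, const imat& mask) {
  const uword R = mask.n_rows;
  mat A(R, R, fill::zeros);
  uword k = 0;
  for (uword j = 0; j < R; ++j)
    for (uword i = 0; i < R; ++i)
      if (mask(i, j) != 0) A(i, j) = theta(k++);
  const uword na = k;
  for (uword r = 0; r < R; ++r)
    A(r, r) = -SELF_RATE * std::exp(theta(na + r));
  return A;
}

// Predicted cross-spectral density cube (R x R x nf), Hermitian per slice.
static cx_cube predict_cube(const vec& theta, const imat& mask,
                            const vec& freqs) {
  const uword R = mask.n_rows;
  const uword nf = freqs.n_elem;
  uword na = accu(mask != 0);
  const mat A = assemble_A_cpp(theta, mask);
  const double log_av = theta(na + R);
  const double beta_v = beta_map(theta(na + R + 1));
  const double log_ae = theta(na + R + 2);
  const double beta_e = beta_map(theta(na + R + 3));
  vec kappa(R), gamma(R);
  for (uword r = 0; r < R; ++r) {
    kappa(r) = KAPPA0 * std::exp(theta(na + R + 4 + r));
    gamma(r) = GAMMA0 * std::exp(theta(na + R + 4 + R + r));
  }
  cx_cube S(R, R, nf);
  const cx_double iunit(0.0, 1.0);
  cx_mat I = eye<cx_mat>(R, R);
  for (uword f = 0; f < nf; ++f) {
    const double w = 2.0 * datum::pi * freqs(f);
    cx_mat T = inv(iunit * w * I - conv_to<cx_mat>::from(A));
    cx_vec h(R);
    for (uword r = 0; r < R; ++r)
      h(r) = kappa(r) / ((iunit * w + kappa(r)) * (iunit * w + gamma(r)));
    cx_mat HT = diagmat(h) * T;
    const double gv = std::exp(log_av) * std::pow(w, -beta_v);
    const double ge = std::exp(log_ae) * std::pow(w, -beta_e);
    cx_mat Sf = gv * (HT * HT.t());        // .t() is conjugate transpose
    Sf.diag() += ge;
    S.slice(f) = 0.5 * (Sf + Sf.t());      // enforce exact Hermitian symmetry
  }
  return S;
}

// Stack a CSD cube into the real feature vector the inversion fits:
// per frequency, real parts of upper triangle incl. diagonal (col-major),
// then imaginary parts of the strict upper triangle.
static vec cube_to_features(const cx_cube& S) {
  const uword R = S.n_rows, nf = S.n_slices;
  const uword nre = R * (R + 1) / 2, nim = R * (R - 1) / 2;
  vec y(nf * (nre + nim));
  uword k = 0;
  for (uword f = 0; f < nf; ++f) {
    for (uword j = 0; j < R; ++j)
      for (uword i = 0; i <= j; ++i) y(k++) = S(i, j, f).real();
    for (uword j = 0; j < R; ++j)
      for (uword i = 0; i < j; ++i) y(k++) = S(i, j, f).imag();
  }
  return y;
}

// Alias-folded prediction: sampled data at interval tr see the continuous
// spectrum folded at multiples of the sampling rate,
// S_obs(f) = sum_k S(f + k/tr) with S(-f) = conj(S(f)).
static cx_cube predict_cube_folded(const vec& theta, const imat& mask,
                                   const vec& freqs, double tr, int kmax) {
  cx_cube S = predict_cube(theta, mask, freqs);
  if (tr <= 0.0 || kmax < 1) return S;
  for (int k = 1; k <= kmax; ++k) {
    vec f_lo = k / tr - freqs;   // negative branch, conjugated
    vec f_hi = k / tr + freqs;
    cx_cube Slo = predict_cube(theta, mask, f_lo);
    cx_cube Shi = predict_cube(theta, mask, f_hi);
    for (uword f = 0; f < freqs.n_elem; ++f)
      S.slice(f) += conj(Slo.slice(f)) + Shi.slice(f);
  }
  return S;
}

// [[Rcpp::export]]
arma::cx_cube cpp_predict_csd(const arma::vec& theta, const arma::imat& mask,
                              const arma::vec& freqs) {
  return predict_cube(theta, mask, freqs);
}

// [[Rcpp::export]]
arma::cx_cube cpp_predict_csd_folded(const arma::vec& theta,
                                     const arma::imat& mask,
                                     const arma::vec& freqs, double tr,
                                     int kmax) {
  return predict_cube_folded(theta, mask, freqs, tr, kmax);
}

// [[Rcpp::export]]
arma::vec cpp_predict_features_folded(const arma::vec& theta,
                                      const arma::imat& mask,
                                      const arma::vec& freqs, double tr,
                                      int kmax) {
  return cube_to_features(predict_cube_folded(theta, mask, freqs, tr, kmax));
}

// [[Rcpp::export]]
arma::mat cpp_jacobian_features_folded(const arma::vec& theta,
                                       const arma::imat& mask,
                                       const arma::vec& freqs, double h,
                                       double tr, int kmax) {
  const uword p = theta.n_elem;
  vec y0 = cube_to_features(predict_cube_folded(theta, mask, freqs, tr, kmax));
  mat J(y0.n_elem, p);
  for (uword k = 0; k < p; ++k) {
    vec tp = theta, tm = theta;
    tp(k) += h;
    tm(k) -= h;
    vec yp = cube_to_features(predict_cube_folded(tp, mask, freqs, tr, kmax));
    vec ym = cube_to_features(predict_cube_folded(tm, mask, freqs, tr, kmax));
    J.col(k) = (yp - ym) / (2.0 * h);
  }
  return J;
}

// [[Rcpp::export]]
arma::vec cpp_predict_features(const arma::vec& theta, const arma::imat& mask,
                               const arma::vec& freqs) {
  return cube_to_features(predict_cube(theta, mask, freqs));
}

// [[Rcpp::export]]
arma::vec cpp_csd_to_features(const arma::cx_cube& S) {
  return cube_to_features(S);
}

// Central-difference Jacobian of the feature map (n_data x n_param).
// [[Rcpp::export]]
arma::mat cpp_jacobian_features(const arma::vec& theta, const arma::imat& mask,
                                const arma::vec& freqs, double h) {
  const uword p = theta.n_elem;
  vec y0 = cube_to_features(predict_cube(theta, mask, freqs));
  mat J(y0.n_elem, p);
  for (uword k = 0; k < p; ++k) {
    vec tp = theta, tm = theta;
    tp(k) += h;
    tm(k) -= h;
    vec yp = cube_to_features(predict_cube(tp, mask, freqs));
    vec ym = cube_to_features(predict_cube(tm, mask, freqs));
    J.col(k) = (yp - ym) / (2.0 * h);
  }
  return J;
}

// Euler integration of dx/dt = A x + v(t); v sampled on the dt grid.
// Returns the state trajectory (n_steps x R), x(0) = 0.
// [[Rcpp::export]]
arma::mat cpp_simulate_lds(const arma::mat& A, const arma::mat& v, double dt) {
  const uword n = v.n_rows, R = A.n_rows;
  mat X(n, R, fill::zeros);
  vec x(R, fill::zeros);
  for (uword t = 0; t < n; ++t) {
    x += dt * (A * x + v.row(t).t());
    if (!x.is_finite()) Rcpp::stop("latent dynamics diverged at step %d", (int)t);
    X.row(t) = x.t();
  }
  return X;
}
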