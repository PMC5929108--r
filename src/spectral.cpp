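// Spectral kernel of the package: predicted cross-spectral density of a
// linear stochastic neuronal model observed through a linearised
// haemodynamic response, its feature vector, and finite-difference
// Jacobians with respect to the model parameter vector.
//
// Parameter vector layout (must match param_map() on the R side):
//   [ off-diagonal A entries, column-major | n self log-factors |
//     log alpha_v | log beta_v | log alpha_e | log beta_e | n transit factors ]
// Self-connections are realised as -0.5 * exp(theta_self), so diagonals of A
// are always negative. Spectral and transit parameters are log-scalings of
// base values carried in the model spec list.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Linearised balloon model transfer function for one region.
// States: vasodilatory signal s, inflow f, volume v, deoxyhaemoglobin q,
// linearised about the resting fixed point; output is the BOLD response to
// a neuronal impulse, in the frequency domain (omega in rad/s).
static cx_vec balloon_one(const vec& omega, double tau, double kappa,
                          double gamma, double alpha, double E0, double V0) {
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const double cf = 1.0 + (1.0 - E0) * std::log(1.0 - E0) / E0;
  cx_vec iw(omega.n_elem);
  for (uword k = 0; k < omega.n_elem; ++k) iw(k) = cx_double(0.0, omega(k));
  cx_vec Ff = 1.0 / (iw % iw + kappa * iw + gamma);
  cx_vec Vv = Ff / (tau * (iw + 1.0 / (tau * alpha)));
  cx_vec Qq = (cf * Ff - (1.0 / alpha - 1.0) * Vv) / (tau * iw + 1.0);
  return V0 * ((k2 - k3) * Vv - (k1 + k2) * Qq);
}

// [[Rcpp::export]]
arma::cx_mat cpp_balloon_transfer(const arma::vec& omega, const arma::vec& tau,
                                  double kappa, double gamma, double alpha,
                                  double E0, double V0) {
  cx_mat K(omega.n_elem, tau.n_elem);
  for (uword j = 0; j < tau.n_elem; ++j)
    K.col(j) = balloon_one(omega, tau(j), kappa, gamma, alpha, E0, V0);
  return K;
}

// G_y(w) = H(w) diag(gv) H(w)^* + diag(ge), H(w) = diag(K(w)) (iwI - A)^{-1}
// gv, ge: nfreq x n spectral densities of endogenous fluctuations and
// observation noise. K: nfreq x n haemodynamic transfer (pass ones for
// a unit observation kernel).
// [[Rcpp::export]]
arma::cx_cube cpp_predict_csd(const arma::mat& A, const arma::vec& omega,
                              const arma::cx_mat& K, const arma::mat& gv,
                              const arma::mat& ge) {
  const uword n = A.n_rows, nf = omega.n_elem;
  cx_cube G(n, n, nf);
  cx_mat I = eye<cx_mat>(n, n);
  cx_mat Ac = conv_to<cx_mat>::from(A);
  for (uword k = 0; k < nf; ++k) {
    cx_mat H = solve(cx_double(0.0, omega(k)) * I - Ac, I);
    cx_vec Kk = K.row(k).st();
    H.each_col() %= Kk;  // row i of H scaled by K_i(w)
    cx_mat M = H * diagmat(conv_to<cx_vec>::from(gv.row(k).t())) * trans(H);
    M.diag() += conv_to<cx_vec>::from(ge.row(k).t());
    G.slice(k) = M;
  }
  return G;
}

// Stack a Hermitian CSD cube into the real feature vector used by the
// inversion: per frequency, Re of the upper triangle including the diagonal
// (column-major), then Im of the strict upper triangle (column-major).
// [[Rcpp::export]]
arma::vec cpp_csd_features(const arma::cx_cube& G) {
  const uword n = G.n_rows, nf = G.n_slices;
  const uword nre = n * (n + 1) / 2, nim = n * (n - 1) / 2;
  vec out(nf * (nre + nim));
  uword pos = 0;
  for (uword k = 0; k < nf; ++k) {
    const cx_mat& S = G.slice(k);
    for (uword j = 0; j < n; ++j)
      for (uword i = 0; i <= j; ++i) out(pos++) = S(i, j).real();
    for (uword j = 1; j < n; ++j)
      for (uword i = 0; i < j; ++i) out(pos++) = S(i, j).imag();
  }
  return out;
}

struct ModelSpec {
  uword n;
  vec omega;
  double kappa, gamma, alphaH, E0, V0;
  double av0, bv0, ae0, be0, tau0;
};

static ModelSpec read_spec(const Rcpp::List& ms) {
  ModelSpec s;
  s.n = Rcpp::as<uword>(ms["n"]);
  s.omega = Rcpp::as<vec>(ms["omega"]);
  s.kappa = Rcpp::as<double>(ms["kappa"]);
  s.gamma = Rcpp::as<double>(ms["gamma"]);
  s.alphaH = Rcpp::as<double>(ms["stiffness"]);
  s.E0 = Rcpp::as<double>(ms["extraction"]);
  s.V0 = Rcpp::as<double>(ms["v0"]);
  s.av0 = Rcpp::as<double>(ms["alpha_v"]);
  s.bv0 = Rcpp::as<double>(ms["beta_v"]);
  s.ae0 = Rcpp::as<double>(ms["alpha_e"]);
  s.be0 = Rcpp::as<double>(ms["beta_e"]);
  s.tau0 = Rcpp::as<double>(ms["transit"]);
  return s;
}

static vec predict_features_theta(const vec& th, const ModelSpec& s) {
  const uword n = s.n;
  mat A(n, n);
  uword pos = 0;
  for (uword j = 0; j < n; ++j)
    for (uword i = 0; i < n; ++i)
      if (i != j) A(i, j) = th(pos++);
  for (uword i = 0; i < n; ++i) A(i, i) = -0.5 * std::exp(th(pos++));
  const double av = s.av0 * std::exp(th(pos++));
  const double bv = s.bv0 * std::exp(th(pos++));
  const double ae = s.ae0 * std::exp(th(pos++));
  const double be = s.be0 * std::exp(th(pos++));
  vec tau(n);
  for (uword i = 0; i < n; ++i) tau(i) = s.tau0 * std::exp(th(pos++));

  cx_mat K = cpp_balloon_transfer(s.omega, tau, s.kappa, s.gamma, s.alphaH,
                                  s.E0, s.V0);
  vec gv = av * pow(s.omega, -bv);
  vec ge = ae * pow(s.omega, -be);

  const uword nf = s.omega.n_elem;
  const uword nre = n * (n + 1) / 2, nim = n * (n - 1) / 2;
  vec out(nf * (nre + nim));
  cx_mat I = eye<cx_mat>(n, n);
  cx_mat Ac = conv_to<cx_mat>::from(A);
  uword fp = 0;
  for (uword k = 0; k < nf; ++k) {
    cx_mat H = solve(cx_double(0.0, s.omega(k)) * I - Ac, I);
    cx_vec Kk = K.row(k).st();
    H.each_col() %= Kk;
    cx_mat M = gv(k) * (H * trans(H));
    M.diag() += ge(k);
    for (uword j = 0; j < n; ++j)
      for (uword i = 0; i <= j; ++i) out(fp++) = M(i, j).real();
    for (uword j = 1; j < n; ++j)
      for (uword i = 0; i < j; ++i) out(fp++) = M(i, j).imag();
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_predict_features(const arma::vec& theta, const Rcpp::List& ms) {
  return predict_features_theta(theta, read_spec(ms));
}

// Central finite-difference Jacobian of the feature vector w.r.t. the free
// parameters (1-based indices in free_idx).
// [[Rcpp::export]]
arma::mat cpp_feature_jacobian(const arma::vec& theta, const Rcpp::List& ms,
                               const arma::uvec& free_idx, double step) {
  ModelSpec s = read_spec(ms);
  vec f0 = predict_features_theta(theta, s);
  mat J(f0.n_elem, free_idx.n_elem);
  for (uword q = 0; q < free_idx.n_elem; ++q) {
    const uword p = free_idx(q) - 1;
    vec tp = theta, tm = theta;
    tp(p) += step;
    tm(p) -= step;
    J.col(q) = (predict_features_theta(tp, s) - predict_features_theta(tm, s)) /
               (2.0 * step);
  }
  return J;
}

// Euler integration of dx/dt = A x + v on a fine grid; V is T x n.
// [[Rcpp::export]]
arma::mat cpp_euler(const arma::mat& A, const arma::mat& V, double dt) {
  const uword T = V.n_rows, n = V.n_cols;
  mat X(T, n, fill::zeros);
  rowvec x(n, fill::zeros);
  for (uword t = 0; t + 1 < T; ++t) {
    x += dt * (x * A.t() + V.row(t));
    X.row(t + 1) = x;
  }
  return X;
}
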