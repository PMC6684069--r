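// Compiled kernels: Kuramoto phase integration, exact-discretisation linear
// state-space sample paths, and the cross-spectral Gaussian log joint used
// by the model fitter. All randomness goes through R's RNG so set.seed()
// governs every simulation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Euler-Maruyama integration of coupled phase oscillators:
//   dphi_i = [2 pi f_i + sum_j K(i,j) sin(phi_j - phi_i)] dt + sigma dW.
// K(i,j) is the influence of oscillator j on i. Returns n_steps x n phases
// (unwrapped radians), first row = phi0.
// [[Rcpp::export]]
arma::mat kuramoto_path_cpp(const arma::mat& K, const arma::vec& f,
                            double dt, int n_steps, double sigma,
                            const arma::vec& phi0) {
  const int n = f.n_elem;
  arma::mat out(n_steps, n);
  arma::vec phi = phi0, dphi(n);
  const double sqdt = std::sqrt(dt);
  out.row(0) = phi.t();
  for (int s = 1; s < n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double drift = 2.0 * M_PI * f(i);
      for (int j = 0; j < n; ++j) {
        if (K(i, j) != 0.0)
          drift += K(i, j) * std::sin(phi(j) - phi(i));
      }
      dphi(i) = drift * dt + sigma * sqdt * R::norm_rand();
    }
    phi += dphi;
    out.row(s) = phi.t();
  }
  return out;
}

// Sample path of x[k+1] = F x[k] + L eps[k], eps ~ N(0, I); returns the
// n_steps x n_keep matrix of the states listed in keep (0-based).
// [[Rcpp::export]]
arma::mat linear_path_cpp(const arma::mat& F, const arma::mat& L,
                          int n_steps, const arma::vec& x0,
                          const arma::uvec& keep) {
  const int d = F.n_rows, m = L.n_cols;
  arma::vec x = x0, eps(m);
  arma::mat out(n_steps, keep.n_elem);
  for (int s = 0; s < n_steps; ++s) {
    for (arma::uword k = 0; k < keep.n_elem; ++k) out(s, k) = x(keep(k));
    for (int j = 0; j < m; ++j) eps(j) = R::norm_rand();
    x = F * x + L * eps;
  }
  (void)d;
  return out;
}

// Build the 2n x 2n drift matrix of the coupled damped-oscillator network.
// Node i has states (z_i, z_i'); z_i'' = -w_i^2 z_i - g_i z_i' + sum_j A(i,j) z_j.
static arma::mat drift_matrix(const arma::vec& gamma, const arma::vec& f0,
                              const arma::mat& A) {
  const int n = gamma.n_elem;
  arma::mat M(2 * n, 2 * n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const double w = 2.0 * M_PI * f0(i);
    M(2 * i, 2 * i + 1) = 1.0;
    M(2 * i + 1, 2 * i) = -w * w;
    M(2 * i + 1, 2 * i + 1) = -gamma(i);
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0.0) M(2 * i + 1, 2 * j) += A(i, j);
  }
  return M;
}

// [[Rcpp::export]]
arma::mat drift_matrix_cpp(const arma::vec& gamma, const arma::vec& f0,
                           const arma::mat& A) {
  return drift_matrix(gamma, f0, A);
}

// Closed-form one-sided cross-spectral density of the observed positions:
//   S(f) = 2 G H(f) Q H(f)^H G^T + s_obs I,  H(f) = (i 2 pi f I - M)^{-1},
// Q the innovation PSD (level q on the velocity states), s_obs a flat
// observation-noise density (units^2/Hz).
static arma::cx_cube model_csd_core(const arma::vec& gamma, const arma::vec& f0,
                                    double q, double s_obs, const arma::mat& A,
                                    const arma::vec& freqs) {
  const int n = gamma.n_elem, d = 2 * n, nf = freqs.n_elem;
  arma::mat M = drift_matrix(gamma, f0, A);
  arma::cx_mat Mc(M, arma::mat(d, d, arma::fill::zeros));
  arma::cx_cube S(n, n, nf);
  arma::cx_mat I(d, d, arma::fill::eye);
  for (int k = 0; k < nf; ++k) {
    const std::complex<double> iw(0.0, 2.0 * M_PI * freqs(k));
    arma::cx_mat H = arma::solve(iw * I - Mc, I);
    // columns of H corresponding to velocity states, rows to position states
    arma::cx_mat Hp(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) Hp(i, j) = H(2 * i, 2 * j + 1);
    arma::cx_mat Sf = 2.0 * q * Hp * Hp.t();  // .t() on cx_mat = conj transpose
    for (int i = 0; i < n; ++i) Sf(i, i) += s_obs;
    S.slice(k) = Sf;
  }
  return S;
}

// [[Rcpp::export]]
arma::cx_cube model_csd_cpp(const arma::vec& gamma, const arma::vec& f0,
                            double q, double s_obs, const arma::mat& A,
                            const arma::vec& freqs) {
  return model_csd_core(gamma, f0, q, s_obs, A, freqs);
}

// Largest real part of the eigenvalues of the drift matrix (stability check).
// [[Rcpp::export]]
double drift_max_re_cpp(const arma::vec& gamma, const arma::vec& f0,
                        const arma::mat& A) {
  arma::cx_vec ev = arma::eig_gen(drift_matrix(gamma, f0, A));
  return arma::real(ev).max();
}

// Negative log joint (cross-spectral likelihood + Gaussian prior on the
// transformed parameters) for one or two experimental conditions.
//
// Likelihood (spec["likelihood"]): 0 = Whittle/complex-Wishart,
//   ll = -K sum_f [log det S_mod(f) + tr(S_mod(f)^-1 S_emp(f))]  (+ const);
// 1 = entry-wise Gaussian on real/imag parts with variance S_ii S_jj / K.
//
// theta layout: [log gamma (n) | log f0 (n) | log q | log s_obs |
//                edge log-strengths (m) | condition deltas (m, only if two
//                conditions)]. Condition u has coupling sign*exp(theta_e +
//                u*delta_e) on the allowed edges.
//
// spec: List(n_nodes, edge_to, edge_from (0-based), sign (+-1), freqs,
//            S (list of cx_cube), V (list of cube of residual variances),
//            K (segments per condition), u (numeric per condition),
//            prior_mu, prior_sd, likelihood)
// [[Rcpp::export]]
double csd_nlj_cpp(const arma::vec& theta, const List& spec) {
  const int n = as<int>(spec["n_nodes"]);
  const int lik = as<int>(spec["likelihood"]);
  const arma::vec Kseg = as<arma::vec>(spec["K"]);
  const arma::uvec eto = as<arma::uvec>(spec["edge_to"]);
  const arma::uvec efrom = as<arma::uvec>(spec["edge_from"]);
  const double sign = as<double>(spec["sign"]);
  const arma::vec freqs = as<arma::vec>(spec["freqs"]);
  const List S_list = spec["S"];
  const List V_list = spec["V"];
  const arma::vec u = as<arma::vec>(spec["u"]);
  const arma::vec pmu = as<arma::vec>(spec["prior_mu"]);
  const arma::vec psd = as<arma::vec>(spec["prior_sd"]);
  const int m = eto.n_elem, ncond = u.n_elem;

  const arma::vec gamma = arma::exp(theta.subvec(0, n - 1));
  const arma::vec f0 = arma::exp(theta.subvec(n, 2 * n - 1));
  const double q = std::exp(theta(2 * n));
  const double s_obs = std::exp(theta(2 * n + 1));

  double ll = 0.0;
  for (int c = 0; c < ncond; ++c) {
    arma::mat A(n, n, arma::fill::zeros);
    for (int e = 0; e < m; ++e) {
      double th = theta(2 * n + 2 + e);
      if (ncond > 1) th += u(c) * theta(2 * n + 2 + m + e);
      A(eto(e), efrom(e)) = sign * std::exp(th);
    }
    const double maxre = (m > 0 || true)
      ? arma::real(arma::eig_gen(drift_matrix(gamma, f0, A))).max()
      : -1.0;
    if (!(maxre < -1e-8) || !std::isfinite(maxre))
      return 1e8 * (1.0 + std::max(0.0, maxre));

    arma::cx_cube Smod = model_csd_core(gamma, f0, q, s_obs, A, freqs);
    const arma::cx_cube Semp = as<arma::cx_cube>(S_list[c]);
    const arma::cube V = as<arma::cube>(V_list[c]);
    const int nf = freqs.n_elem;
    const double K = Kseg(c);
    for (int k = 0; k < nf; ++k) {
      if (lik == 0) {
        const arma::cx_mat Sm = Smod.slice(k);
        double ld;
        if (!arma::log_det_sympd(ld, Sm) || !std::isfinite(ld)) return 1e8;
        const arma::cx_mat W = arma::solve(Sm, Semp.slice(k));
        ll += -K * (ld + std::real(arma::trace(W)));
      } else {
        for (int i = 0; i < n; ++i) {
          const double v = V(i, i, k);
          const double r = std::real(Semp(i, i, k)) - std::real(Smod(i, i, k));
          ll += -0.5 * r * r / v - 0.5 * std::log(2.0 * M_PI * v);
          for (int j = i + 1; j < n; ++j) {
            const double vh = 0.5 * V(i, j, k);
            const std::complex<double> d = Semp(i, j, k) - Smod(i, j, k);
            ll += -0.5 * (d.real() * d.real() + d.imag() * d.imag()) / vh
                  - std::log(2.0 * M_PI * vh);
          }
        }
      }
    }
  }

  double lp = 0.0;
  for (arma::uword i = 0; i < theta.n_elem; ++i) {
    const double z = (theta(i) - pmu(i)) / psd(i);
    lp += -0.5 * z * z - std::log(psd(i)) - 0.5 * std::log(2.0 * M_PI);
  }
  const double nlj = -(ll + lp);
  return std::isfinite(nlj) ? nlj : 1e8;
}
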