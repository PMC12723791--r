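// Single-site ensemble integrator and impulse-response estimator for the
// dynamical mean-field theory of the gated network.
//
// Effective process per sample path (condensed-pattern frame, xi = +1):
//   dx/dt = sigma(z) * [ -x + (g/sqrt(alpha)) m(t) + eta_x(t)
//                        + alpha * Int du G(t,u) phi(u) ]
//   tau_z dz/dt = -z + eta_z(t)
// where G is the resolvent memory kernel (1/dt-scaled diagonal carries the
// instantaneous delta part) and eta_x, eta_z are colored Gaussian noises
// supplied by the caller. The gate never responds to the x-perturbation
// (z is autonomous), so response reruns reuse the stored sigma paths.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double gate1(double z, double gamma, bool gamma_inf) {
  if (gamma_inf) return z > 0.0 ? 1.0 : (z == 0.0 ? 0.5 : 0.0);
  if (gamma == 0.0) return 0.5;
  return 1.0 / (1.0 + std::exp(-gamma * z));
}

// [[Rcpp::export]]
Rcpp::List cpp_dmft_paths(const arma::mat& eta_x, const arma::mat& eta_z,
                          const arma::vec& x0, const arma::vec& z0,
                          const arma::vec& m, const arma::mat& G,
                          double kappa_m, double alpha,
                          double gamma, bool gamma_inf,
                          double tau_z, double dt) {
  const uword M = eta_x.n_rows, L = eta_x.n_cols;
  mat x(M, L), phi(M, L), sig(M, L);
  vec phirow(L);
  for (uword p = 0; p < M; ++p) {
    double xc = x0[p], zc = z0[p];
    for (uword k = 0; k < L; ++k) {
      x(p, k) = xc;
      double ph = std::tanh(xc);
      phi(p, k) = ph; phirow[k] = ph;
      double s = gate1(zc, gamma, gamma_inf);
      sig(p, k) = s;
      if (k + 1 < L) {
        double hr = dt * dot(G.row(k).head(k + 1), phirow.head(k + 1));
        double drift = -xc + kappa_m * m[k] + eta_x(p, k) + alpha * hr;
        xc += dt * s * drift;
        zc += (dt / tau_z) * (-zc + eta_z(p, k));
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("phi") = phi,
                            Rcpp::Named("sig") = sig);
}

// Impulse-response estimate R(t, t') = [<phi(t)>_pert - <phi(t)>] / eps with
// an impulse of area eps applied inside the gated bracket at t', using common
// random numbers (the same noise paths as the unperturbed run).
// [[Rcpp::export]]
arma::mat cpp_dmft_response(const arma::mat& x, const arma::mat& phi,
                            const arma::mat& sig, const arma::mat& eta_x,
                            const arma::vec& m, const arma::mat& G,
                            double kappa_m, double alpha, double dt,
                            double eps, int m_resp) {
  const uword L = x.n_cols;
  const uword M = std::min((uword)m_resp, x.n_rows);
  if (eps == 0.0) Rcpp::stop("eps must be nonzero");
  mat R(L, L, fill::zeros);
  vec hr0(L), dphi(L);
  for (uword p = 0; p < M; ++p) {
    // unperturbed retarded field of this path
    for (uword k = 0; k < L; ++k)
      hr0[k] = dt * dot(G.row(k).head(k + 1), phi.row(p).head(k + 1).t());
    for (uword j = 0; j + 1 < L; ++j) {
      // impulse at grid time j: x(j+1) shifts by sigma(j) * eps
      double xc = x(p, j + 1) + sig(p, j) * eps;
      for (uword k = j + 1; k < L; ++k) {
        double ph = std::tanh(xc);
        double d = ph - phi(p, k);
        dphi[k] = d;
        R(k, j) += d;
        if (k + 1 < L) {
          double corr = 0.0;
          for (uword u = j + 1; u <= k; ++u) corr += G(k, u) * dphi[u];
          double drift = -xc + kappa_m * m[k] + eta_x(p, k) +
                         alpha * (hr0[k] + dt * corr);
          xc += dt * sig(p, k) * drift;
        }
      }
    }
  }
  R /= (eps * (double)M);
  return R;
}
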