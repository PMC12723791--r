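// Many-body Euler integrator for the two-layer gated associative memory
// network. The Hebbian drive uses the low-rank factorisation
// (g/sqrt(PN)) * Xi^T (Xi phi); the gate multiplies the whole x-drift so a
// closed gate (sigma = 0) freezes the neuron bit-exactly.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline vec gate_vec(const vec& z, double gamma, bool gamma_inf) {
  if (gamma_inf) {
    vec s(z.n_elem);
    for (uword i = 0; i < z.n_elem; ++i)
      s[i] = (z[i] > 0.0) ? 1.0 : (z[i] == 0.0 ? 0.5 : 0.0);
    return s;
  }
  if (gamma == 0.0) return vec(z.n_elem, fill::value(0.5));
  return 1.0 / (1.0 + exp(-gamma * z));
}

// [[Rcpp::export]]
Rcpp::List cpp_integrate(const arma::mat& Xi, const arma::mat& W,
                         const arma::vec& x0, const arma::vec& z0,
                         double g, double gamma, bool gamma_inf, bool has_W,
                         double tau_z, double dt, int n_steps,
                         int record_every, double conv_tol,
                         bool record_gate, bool record_x,
                         const arma::mat& tracked) {
  const uword N = x0.n_elem;
  const uword P = Xi.n_rows;
  const uword K = tracked.n_rows;
  const double pre = g / std::sqrt((double)P * (double)N);
  const bool subpop = gamma_inf && K > 0;

  const int n_rec_max = n_steps / record_every + 2;
  mat m_rec(n_rec_max, K, fill::zeros);
  vec t_rec(n_rec_max, fill::zeros);
  vec mF(n_rec_max), mA(n_rec_max), rF(n_rec_max), rA(n_rec_max);
  mF.fill(datum::nan); mA.fill(datum::nan); rF.fill(datum::nan); rA.fill(datum::nan);
  mat gt; if (record_gate) gt.set_size(n_rec_max, N);
  mat xs; if (record_x) xs.set_size(n_rec_max, N);

  vec x = x0, z = z0;
  int n_rec = 0;
  bool converged = false;
  int steps_done = 0;

  auto record = [&](int step) {
    vec phi = tanh(x);
    vec sig = gate_vec(z, gamma, gamma_inf);
    for (uword k = 0; k < K; ++k)
      m_rec(n_rec, k) = dot(tracked.row(k).t(), phi) / (double)N;
    t_rec[n_rec] = step * dt;
    if (subpop) {
      // closed population: gate exactly zero (z < 0)
      uword nF = 0; double sF = 0.0, sA = 0.0;
      const rowvec xi1 = tracked.row(0);
      for (uword i = 0; i < N; ++i) {
        double v = xi1[i] * phi[i];
        if (sig[i] == 0.0) { ++nF; sF += v; } else { sA += v; }
      }
      uword nA = N - nF;
      rF[n_rec] = (double)nF / N;
      rA[n_rec] = (double)nA / N;
      mF[n_rec] = nF ? sF / nF : datum::nan;
      mA[n_rec] = nA ? sA / nA : datum::nan;
    }
    if (record_gate) gt.row(n_rec) = sig.t();
    if (record_x) xs.row(n_rec) = x.t();
    ++n_rec;
  };

  record(0);

  vec phi(N), sig(N), drive(N), drift(N);
  for (int step = 1; step <= n_steps; ++step) {
    phi = tanh(x);
    drive = pre * (Xi.t() * (Xi * phi));
    sig = gate_vec(z, gamma, gamma_inf);
    drift = sig % (-x + drive);
    x += dt * drift;
    if (has_W)
      z += (dt / tau_z) * (-z + (W * phi) / std::sqrt((double)N));
    if (!x.is_finite() || !z.is_finite())
      Rcpp::stop("non-finite state at t = %f (overflow in Euler update)", step * dt);
    steps_done = step;
    bool at_rec = (step % record_every == 0);
    double vmax = conv_tol > 0 ? abs(drift).max() : datum::inf;
    if (conv_tol > 0 && vmax < conv_tol) converged = true;
    if (at_rec || converged || step == n_steps) record(step);
    if (converged) break;
  }

  m_rec.resize(n_rec, K);
  t_rec.resize(n_rec);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("times") = t_rec,
    Rcpp::Named("m") = m_rec,
    Rcpp::Named("x_final") = x,
    Rcpp::Named("z_final") = z,
    Rcpp::Named("steps") = steps_done,
    Rcpp::Named("converged") = converged);
  if (subpop) {
    out["mF"] = vec(mF.head(n_rec));
    out["mA"] = vec(mA.head(n_rec));
    out["rhoF"] = vec(rF.head(n_rec));
    out["rhoA"] = vec(rA.head(n_rec));
  }
  if (record_gate) { gt.resize(n_rec, N); out["gate_trace"] = gt; }
  if (record_x) { xs.resize(n_rec, N); out["x_snapshots"] = xs; }
  return out;
}
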