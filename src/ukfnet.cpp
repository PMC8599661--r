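// Compiled core: network drift, RK4 transition map, stochastic simulation,
// and the unscented Kalman filter loop for the (optionally parameter-
// augmented) oscillator model. State layout is (x1, y1, z1, ..., xN, yN, zN)
// followed by q coupling parameters when the state is augmented.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct OscPars {
  double a1, a2, a3, beta, Gamma, gamma, delta, phi, eta, mu, Vth;
};

static OscPars as_pars(const Rcpp::List& p) {
  OscPars o;
  o.a1 = p["alpha1"]; o.a2 = p["alpha2"]; o.a3 = p["alpha3"];
  o.beta = p["beta"]; o.Gamma = p["Gamma"]; o.gamma = p["gamma"];
  o.delta = p["delta"]; o.phi = p["phi"]; o.eta = p["eta"];
  o.mu = p["mu"]; o.Vth = p["v_th"];
  return o;
}

static inline double g_fun(double x, double Vth, double mu) {
  return (x > Vth) ? mu * (x - Vth) : 0.0;
}

// du/dt for the full network; W is the effective coupling-weight matrix
// (K * A, or per-ordered-pair couplings); phi multiplies the coupling sum.
static void drift_net(const vec& u, const OscPars& P, const mat& W, vec& du) {
  const uword N = W.n_rows;
  for (uword i = 0; i < N; ++i) {
    const double x = u[3 * i], y = u[3 * i + 1], z = u[3 * i + 2];
    double c = 0.0;
    for (uword j = 0; j < N; ++j) {
      const double w = W(i, j);
      if (w != 0.0) c += w * (u[3 * j + 1] - y);
    }
    du[3 * i]     = -P.a1 * (x + P.beta * y + P.Gamma * z);
    du[3 * i + 1] = -P.a2 * (-P.gamma * x + (1.0 - P.delta) * y - P.phi * c);
    du[3 * i + 2] = -P.a3 * (-P.eta * g_fun(x, P.Vth, P.mu) + z);
  }
}

static void rk4_net(const vec& u, double dt, const OscPars& P, const mat& W,
                    vec& out, vec& k1, vec& k2, vec& k3, vec& k4, vec& tmp) {
  drift_net(u, P, W, k1);
  tmp = u + 0.5 * dt * k1; drift_net(tmp, P, W, k2);
  tmp = u + 0.5 * dt * k2; drift_net(tmp, P, W, k3);
  tmp = u + dt * k3;       drift_net(tmp, P, W, k4);
  out = u + (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// [[Rcpp::export(name = ".cpp_drift")]]
arma::vec cpp_drift(const arma::vec& state, const Rcpp::List& pars,
                    const arma::mat& W) {
  const OscPars P = as_pars(pars);
  vec du(state.n_elem);
  drift_net(state, P, W, du);
  return du;
}

// [[Rcpp::export(name = ".cpp_rk4_step")]]
arma::vec cpp_rk4_step(const arma::vec& state, double dt,
                       const Rcpp::List& pars, const arma::mat& W) {
  const OscPars P = as_pars(pars);
  const uword d = state.n_elem;
  vec out(d), k1(d), k2(d), k3(d), k4(d), tmp(d);
  rk4_net(state, dt, P, W, out, k1, k2, k3, k4, tmp);
  return out;
}

// Iterates u_{k+1} = rk4(u_k) + omega_k. `noise` holds the pre-drawn
// process-noise increments, one row per completed step ((n_steps-1) x 3N).
// [[Rcpp::export(name = ".cpp_simulate")]]
arma::mat cpp_simulate(const arma::vec& init, int n_steps, double dt,
                       const Rcpp::List& pars, const arma::mat& W,
                       const arma::mat& noise) {
  const OscPars P = as_pars(pars);
  const uword d = init.n_elem;
  mat out(n_steps, d);
  vec u = init, unew(d), k1(d), k2(d), k3(d), k4(d), tmp(d);
  out.row(0) = u.t();
  for (int k = 1; k < n_steps; ++k) {
    rk4_net(u, dt, P, W, unew, k1, k2, k3, k4, tmp);
    if (noise.n_rows > 0) unew += noise.row(k - 1).t();
    if (!unew.is_finite())
      Rcpp::stop("simulation diverged (non-finite state) at step %d", k + 1);
    out.row(k) = unew.t();
    u = unew;
  }
  return out;
}

// Cholesky of P (lower) with escalating diagonal jitter. Returns the number
// of jitter escalations used; -1 signals failure.
static int chol_jitter(const mat& P, mat& L) {
  if (chol(L, P, "lower")) return 0;
  double eps = 1e-12;
  const double scale = std::max(1.0, double(trace(P)) / P.n_rows);
  for (int t = 1; t <= 7; ++t) {
    if (chol(L, P + (eps * scale) * eye(size(P)), "lower")) return t;
    eps *= 10.0;
    if (eps > 1e-6 * 10.0) break;
  }
  return -1;
}

// UKF over the oscillator model with q augmented coupling parameters.
//
// meas:   n x m observation matrix (one row per step)
// obs:    0-based indices of the observed state components
// cidx:   N x N integer matrix; entry r > 0 means W(i,j) = p[r-1] (the r-th
//         augmented parameter), entry 0 means W(i,j) = B(i,j) (known value)
// B:      known coupling weights where cidx == 0
// Qe:     (3N+q) x (3N+q) process covariance (parameter block zero)
// Rm:     m x m measurement covariance
// m0,P0:  initial belief
// Sigma-point spread follows the scaled unscented transform with
// (alpha, beta, kappa).
// [[Rcpp::export(name = ".cpp_ukf_model")]]
Rcpp::List cpp_ukf_model(const arma::mat& meas, const arma::uvec& obs,
                         double dt, const Rcpp::List& pars,
                         const arma::imat& cidx, const arma::mat& B, int q,
                         const arma::mat& Qe, const arma::mat& Rm,
                         const arma::vec& m0, const arma::mat& P0,
                         double alpha, double beta, double kappa) {
  const OscPars P = as_pars(pars);
  const uword n = meas.n_rows, m = meas.n_cols;
  const uword d = m0.n_elem;          // 3N + q
  const uword N = cidx.n_rows;
  const uword nd = 3 * N;             // dynamical substate dimension
  const uword ns = 2 * d + 1;         // sigma points

  const double c = alpha * alpha * (double(d) + kappa);
  const double lambda = c - double(d);
  vec wm(ns), wc(ns);
  wm.fill(1.0 / (2.0 * c));
  wc.fill(1.0 / (2.0 * c));
  wm[0] = lambda / c;
  wc[0] = lambda / c + (1.0 - alpha * alpha + beta);
  const double sc = std::sqrt(c);

  mat mean_out(n, d), sd_out(n, d);
  vec mk = m0;
  mat Pk = P0;
  mat L, X(d, ns), Xp(d, ns), Z(m, ns);
  vec k1(nd), k2(nd), k3(nd), k4(nd), tmp(nd), usub(nd), unew(nd);
  mat W(N, N);
  int jitter_events = 0, skipped_updates = 0;

  for (uword k = 0; k < n; ++k) {
    // --- sigma points from previous belief
    int j = chol_jitter(Pk, L);
    if (j < 0)
      Rcpp::stop("covariance not positive definite after maximum jitter at step %d", k + 1);
    if (j > 0) ++jitter_events;
    X.col(0) = mk;
    for (uword i = 0; i < d; ++i) {
      X.col(1 + i)     = mk + sc * L.col(i);
      X.col(1 + d + i) = mk - sc * L.col(i);
    }

    // --- propagate through the transition map (RK4 on the dynamical
    //     substate using that point's own parameter values; parameters copied)
    for (uword s = 0; s < ns; ++s) {
      for (uword i = 0; i < N; ++i)
        for (uword jj = 0; jj < N; ++jj) {
          const int r = cidx(i, jj);
          W(i, jj) = (r > 0) ? X(nd + (uword)(r - 1), s) : B(i, jj);
        }
      usub = X.col(s).head(nd);
      rk4_net(usub, dt, P, W, unew, k1, k2, k3, k4, tmp);
      Xp.col(s).head(nd) = unew;
      if (q > 0) Xp.col(s).tail(q) = X.col(s).tail(q);
    }
    if (!Xp.is_finite())
      Rcpp::stop("filter diverged (non-finite sigma point) at step %d", k + 1);

    vec mp = Xp * wm;
    mat D = Xp.each_col() - mp;
    mat Pp = D * diagmat(wc) * D.t() + Qe;
    Pp = 0.5 * (Pp + Pp.t());

    // --- redraw sigma points from the predicted belief
    j = chol_jitter(Pp, L);
    if (j < 0)
      Rcpp::stop("predicted covariance not positive definite after maximum jitter at step %d", k + 1);
    if (j > 0) ++jitter_events;
    X.col(0) = mp;
    for (uword i = 0; i < d; ++i) {
      X.col(1 + i)     = mp + sc * L.col(i);
      X.col(1 + d + i) = mp - sc * L.col(i);
    }

    // --- measurement update (observation map selects components)
    for (uword s = 0; s < ns; ++s)
      for (uword i = 0; i < m; ++i) Z(i, s) = X(obs[i], s);
    vec zp = Z * wm;
    mat Dz = Z.each_col() - zp;
    mat Dx = X.each_col() - mp;
    mat S = Dz * diagmat(wc) * Dz.t() + Rm;
    S = 0.5 * (S + S.t());
    mat Cxz = Dx * diagmat(wc) * Dz.t();

    mat K;
    const bool ok = solve(K, S.t(), Cxz.t());  // K = Cxz * inv(S)
    if (!ok) {
      ++skipped_updates;
      mk = mp;
      Pk = Pp;
    } else {
      K = K.t();
      mk = mp + K * (meas.row(k).t() - zp);
      Pk = Pp - K * S * K.t();
      Pk = 0.5 * (Pk + Pk.t());
    }
    if (!mk.is_finite())
      Rcpp::stop("filter diverged (non-finite estimate) at step %d", k + 1);

    mean_out.row(k) = mk.t();
    sd_out.row(k) = sqrt(clamp(Pk.diag(), 0.0, datum::inf)).t();
  }

  return Rcpp::List::create(
      Rcpp::Named("mean") = mean_out, Rcpp::Named("sd") = sd_out,
      Rcpp::Named("final_cov") = Pk,
      Rcpp::Named("jitter_events") = jitter_events,
      Rcpp::Named("skipped_updates") = skipped_updates);
}
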