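// Kalman filter / RTS smoother core for the latent LDS
//   s_k = M s_{k-1} + n_k,   n_k ~ N(0, N)
//   y_k = P s_k     + r_k,   r_k ~ N(0, R), R diagonal
// Measurement updates use the information form so the per-bin cost is
// O(E d^2) rather than O(E^3); the marginal log-likelihood comes from the
// prediction-error decomposition evaluated with the matrix-inversion and
// determinant lemmas (R diagonal).
//
// The optional steady-state mode freezes the filter and smoother gain
// matrices once the predicted-state covariance has converged, after which
// each bin costs only the mean recursions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
Rcpp::List cpp_kalman_smooth(const arma::mat& y,      // T x E
                             const arma::mat& M,      // d x d
                             const arma::mat& N,      // d x d
                             const arma::mat& P,      // E x d
                             const arma::vec& Rdiag,  // E
                             const arma::vec& pi1,    // d
                             const arma::mat& S1,     // d x d
                             const bool steady_state,
                             const double ss_tol,
                             const bool want_covs) {
  const uword T = y.n_rows, E = y.n_cols, d = M.n_rows;
  if (P.n_rows != E || P.n_cols != d) Rcpp::stop("dimension mismatch in P");

  const mat Mt = M.t();
  const vec Rinv = 1.0 / Rdiag;
  const mat PtRi = P.t() * diagmat(Rinv);   // d x E
  const mat PtRiP = PtRi * P;               // d x d
  const double logdetR = accu(log(Rdiag));

  mat xp(d, T), xf(d, T);                   // predicted / filtered means
  vec llk(T);

  // covariance storage: in steady-state mode only the pre-freeze segment
  // is stored, afterwards frozen matrices are reused.
  std::vector<mat> Vf_store, Vpinv_store, Vp_store;
  Vf_store.reserve(steady_state ? 512 : T);

  mat Vpred, Vfilt, Vpinv, Vpred_prev(d, d, fill::value(datum::inf));
  mat Vf_frozen, Vpinv_frozen, Vp_frozen, J_frozen;
  double ld_frozen = 0.0;                   // log|S_k| once frozen
  uword freeze_at = T + 1;                  // first frozen index (1-based)
  bool frozen = false;

  double loglik = 0.0;

  const mat yt = y.t();                  // E x T, column access per bin
  vec x_pred_buf(d), e_buf(E), g_buf(d), Vfg_buf(d);

  for (uword k = 0; k < T; ++k) {
    if (!frozen) {
      if (k == 0) {
        Vpred = S1;
      } else {
        Vpred = M * Vfilt * Mt + N;
      }
      Vpred = 0.5 * (Vpred + Vpred.t());
      if (k > 0 && steady_state &&
          abs(Vpred - Vpred_prev).max() <= ss_tol * (1.0 + abs(Vpred).max())) {
        frozen = true;
        freeze_at = k + 1;
      }
      Vpred_prev = Vpred;
      Vpinv = inv_sympd(Vpred);
      mat A = Vpinv + PtRiP;
      Vfilt = inv_sympd(A);
      Vfilt = 0.5 * (Vfilt + Vfilt.t());
      double ld;
      double sign;
      log_det(ld, sign, Vpred);
      double ld2, sign2;
      log_det(ld2, sign2, A);
      double logdetS = logdetR + ld + ld2;
      if (frozen) {
        Vf_frozen = Vfilt; Vpinv_frozen = Vpinv; Vp_frozen = Vpred;
        ld_frozen = logdetS;
        J_frozen = Vfilt * Mt * Vpinv;   // gain used from freeze_at onward
      }
      if (!steady_state || !frozen) {
        Vf_store.push_back(Vfilt);
        Vpinv_store.push_back(Vpinv);
        Vp_store.push_back(Vpred);
      }
      // log|S_k| for this bin
      llk(k) = logdetS;
    } else {
      llk(k) = ld_frozen;
    }

    const mat& Vf_k = frozen ? Vf_frozen : Vfilt;
    if (k == 0) x_pred_buf = pi1; else x_pred_buf = M * xf.col(k - 1);
    e_buf = yt.col(k) - P * x_pred_buf;
    g_buf = PtRi * e_buf;
    Vfg_buf = Vf_k * g_buf;
    xf.col(k) = x_pred_buf + Vfg_buf;
    xp.col(k) = x_pred_buf;
    double quad = dot(square(e_buf), Rinv) - dot(g_buf, Vfg_buf);
    llk(k) = -0.5 * (E * LOG2PI + llk(k) + quad);
    loglik += llk(k);
  }

  // smoother gains J_k = Vf_k M' Vpinv_{k+1}, k = 1..T-1 (1-based)
  auto Vf_at = [&](uword k) -> const mat& {           // k is 0-based
    return (steady_state && k + 1 >= freeze_at) ? Vf_frozen : Vf_store[k];
  };
  auto Vpinv_at = [&](uword k) -> const mat& {
    return (steady_state && k + 1 >= freeze_at) ? Vpinv_frozen : Vpinv_store[k];
  };
  auto Vpred_at = [&](uword k) -> const mat& {
    return (steady_state && k + 1 >= freeze_at) ? Vp_frozen : Vp_store[k];
  };

  // backward pass: means in the loop; covariance sums accumulated
  // in-place, mean outer-product sums via BLAS afterwards
  mat xs(d, T);
  xs.col(T - 1) = xf.col(T - 1);
  mat Vs_next = Vf_at(T - 1);

  mat Vall(d, d, fill::zeros);     // sum of smoothed covariances, k=1..T
  mat Vhead(d, d, fill::zeros);    // k=2..T
  mat Vtail(d, d, fill::zeros);    // k=1..T-1
  mat Vlagsum(d, d, fill::zeros);  // sum Cov(s_k, s_{k-1} | Y), k=2..T

  cube Vs_cube, Vlag_cube;
  if (want_covs) { Vs_cube.set_size(d, d, T); Vlag_cube.set_size(d, d, T); Vlag_cube.zeros(); }

  Vall += Vs_next;
  if (T > 1) Vhead += Vs_next;
  if (want_covs) Vs_cube.slice(T - 1) = Vs_next;

  mat Vs_k(d, d), J_k(d, d), Vlag(d, d); // Vlag = Cov(s_{k+1}, s_k | Y)
  bool sm_frozen = false;                // smoother covariances converged
  mat Vs_frozen, Vlag_frozen, Vs_prev(d, d, fill::value(datum::inf));
  vec dxs(d);

  for (uword k = T - 1; k-- > 0;) { // k = T-2 .. 0 (0-based index of s_k)
    bool use_frozen_gain = steady_state && (k + 1 >= freeze_at) && (k + 2 >= freeze_at);
    bool covs_fixed = sm_frozen && use_frozen_gain;
    if (!covs_fixed) {
      if (use_frozen_gain) J_k = J_frozen;
      else J_k = Vf_at(k) * Mt * Vpinv_at(k + 1);
    }
    dxs = xs.col(k + 1) - xp.col(k + 1);
    xs.col(k) = xf.col(k) + J_k * dxs;

    if (covs_fixed) {
      Vs_k = Vs_frozen;
      Vlag = Vlag_frozen;
    } else {
      Vs_k = Vf_at(k) + J_k * (Vs_next - Vpred_at(k + 1)) * J_k.t();
      Vs_k = 0.5 * (Vs_k + Vs_k.t());
      Vlag = Vs_next * J_k.t();
      if (steady_state && use_frozen_gain &&
          abs(Vs_k - Vs_prev).max() <= ss_tol * (1.0 + abs(Vs_k).max())) {
        sm_frozen = true; Vs_frozen = Vs_k; Vlag_frozen = Vlag;
      }
      Vs_prev = Vs_k;
    }

    Vall += Vs_k;
    Vtail += Vs_k;
    if (k > 0) Vhead += Vs_k;
    Vlagsum += Vlag;
    if (want_covs) { Vs_cube.slice(k) = Vs_k; Vlag_cube.slice(k + 1) = Vlag; }

    Vs_next = Vs_k;
  }

  mat S_all = Vall + xs * xs.t();
  mat S_head(d, d, fill::zeros), S_tail(d, d, fill::zeros),
      S_lag(d, d, fill::zeros);
  if (T > 1) {
    const mat xs_head = xs.cols(1, T - 1);
    const mat xs_tail = xs.cols(0, T - 2);
    S_head = Vhead + xs_head * xs_head.t();
    S_tail = Vtail + xs_tail * xs_tail.t();
    S_lag = Vlagsum + xs_head * xs_tail.t();
  }
  mat Sys = yt * xs.t();           // E x d: sum_k y_k E[s_k]'

  mat V1 = Vs_next; // smoothed covariance at k=1

  return Rcpp::List::create(
    Rcpp::Named("xs") = xs.t(),
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("ll_bins") = llk,
    Rcpp::Named("S_all") = S_all,
    Rcpp::Named("S_head") = S_head,
    Rcpp::Named("S_tail") = S_tail,
    Rcpp::Named("S_lag") = S_lag,
    Rcpp::Named("Sys") = Sys,
    Rcpp::Named("x1") = xs.col(0),
    Rcpp::Named("V1") = V1,
    Rcpp::Named("Vs") = want_covs ? Rcpp::wrap(Vs_cube) : R_NilValue,
    Rcpp::Named("Vlag") = want_covs ? Rcpp::wrap(Vlag_cube) : R_NilValue,
    Rcpp::Named("freeze_index") = (double)(frozen ? freeze_at : 0));
}

// Marginal log-likelihood only (same forward pass, no storage).
// [[Rcpp::export]]
double cpp_kalman_loglik(const arma::mat& y, const arma::mat& M,
                         const arma::mat& N, const arma::mat& P,
                         const arma::vec& Rdiag, const arma::vec& pi1,
                         const arma::mat& S1) {
  const uword T = y.n_rows, E = y.n_cols, d = M.n_rows;
  const mat Mt = M.t();
  const vec Rinv = 1.0 / Rdiag;
  const mat PtRi = P.t() * diagmat(Rinv);
  const mat PtRiP = PtRi * P;
  const double logdetR = accu(log(Rdiag));
  vec xf(d);
  mat Vfilt(d, d);
  double loglik = 0.0;
  for (uword k = 0; k < T; ++k) {
    vec x_pred; mat Vpred;
    if (k == 0) { x_pred = pi1; Vpred = S1; }
    else { x_pred = M * xf; Vpred = M * Vfilt * Mt + N; }
    Vpred = 0.5 * (Vpred + Vpred.t());
    mat Vpinv = inv_sympd(Vpred);
    mat A = Vpinv + PtRiP;
    Vfilt = inv_sympd(A);
    vec e = y.row(k).t() - P * x_pred;
    vec g = PtRi * e;
    xf = x_pred + Vfilt * g;
    double ld, s1s, ld2, s2s;
    log_det(ld, s1s, Vpred);
    log_det(ld2, s2s, A);
    double quad = dot(square(e), Rinv) - as_scalar(g.t() * Vfilt * g);
    loglik += -0.5 * (E * LOG2PI + logdetR + ld + ld2 + quad);
  }
  return loglik;
}

// Steady-state innovation-form filter:
//   s_k = M s_{k-1} + K (y_k - P M s_{k-1}),  s_0 = x0.
// Used for decoding (NDF family and, with kinematic matrices, FIT-KF).
// [[Rcpp::export]]
arma::mat cpp_ss_filter(const arma::mat& y, const arma::mat& M,
                        const arma::mat& K, const arma::mat& P,
                        const arma::vec& x0) {
  const uword T = y.n_rows, d = M.n_rows;
  mat out(d, T);
  vec s = x0;
  const mat PM = P * M;
  for (uword k = 0; k < T; ++k) {
    vec s_pred = M * s;
    s = s_pred + K * (y.row(k).t() - P * s_pred);
    out.col(k) = s;
  }
  return out.t();
}

// Time-varying Kalman filter means (oracle for the steady-state decoder).
// [[Rcpp::export]]
arma::mat cpp_kf_filter_means(const arma::mat& y, const arma::mat& M,
                              const arma::mat& N, const arma::mat& P,
                              const arma::vec& Rdiag, const arma::vec& pi1,
                              const arma::mat& S1) {
  const uword T = y.n_rows, d = M.n_rows;
  const mat Mt = M.t();
  const vec Rinv = 1.0 / Rdiag;
  const mat PtRi = P.t() * diagmat(Rinv);
  const mat PtRiP = PtRi * P;
  mat out(d, T);
  vec xf(d); mat Vfilt(d, d);
  for (uword k = 0; k < T; ++k) {
    vec x_pred; mat Vpred;
    if (k == 0) { x_pred = M * pi1; Vpred = M * S1 * Mt + N; }
    else { x_pred = M * xf; Vpred = M * Vfilt * Mt + N; }
    Vpred = 0.5 * (Vpred + Vpred.t());
    mat Vpinv = inv_sympd(Vpred);
    Vfilt = inv_sympd(Vpinv + PtRiP);
    vec e = y.row(k).t() - P * x_pred;
    xf = x_pred + Vfilt * (PtRi * e);
    out.col(k) = xf;
  }
  return out.t();
}
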