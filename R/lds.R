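#' Latent LDS parameter set
#'
#' Parameters of the linear dynamical system
#' `s_k = M s_{k-1} + n_k`, `y_k = P s_k + r_k`, with diagonal process and
#' observation noise covariances `N` and `R`, and initial state
#' `s_1 ~ N(pi1, S1)`. Because binned spike counts have a positive
#' baseline while the model is zero-mean, the training mean of the
#' observations is carried along in `y_mean` and subtracted before any
#' filtering or smoothing.
#'
#' @param M d x d dynamics matrix.
#' @param N d x d diagonal process-noise covariance.
#' @param P E x d observation matrix.
#' @param R E x E diagonal observation-noise covariance.
#' @param pi1 length-d initial state mean.
#' @param S1 d x d initial state covariance (symmetric PSD).
#' @param y_mean length-E observation mean subtracted before filtering
#'   (default zeros).
#' @param electrode_ids optional electrode labels (length E).
#' @param meta optional list of fit metadata.
#' @return An object of class `lds_params`.
#' @export
lds_params <- function(M, N, P, R, pi1, S1, y_mean = NULL,
                       electrode_ids = NULL, meta = list()) {
  M <- as_num_matrix(M, "M"); N <- as_num_matrix(N, "N")
  P <- as_num_matrix(P, "P"); R <- as_num_matrix(R, "R")
  d <- nrow(M); E <- nrow(P)
  assert_that(ncol(M) == d && all(dim(N) == d) && ncol(P) == d &&
                all(dim(R) == E) && length(pi1) == d && all(dim(S1) == d),
              "inconsistent LDS dimensions")
  assert_that(all(N[row(N) != col(N)] == 0) && all(diag(N) > 0),
              "N must be diagonal with positive entries")
  assert_that(all(R[row(R) != col(R)] == 0) && all(diag(R) > 0),
              "R must be diagonal with positive entries")
  S1 <- (S1 + t(S1)) / 2
  assert_that(min(eigen(S1, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8,
              "S1 must be positive semidefinite")
  y_mean <- y_mean %||% numeric(E)
  assert_that(length(y_mean) == E, "y_mean must have length E")
  structure(list(M = M, N = N, P = P, R = R, pi1 = as.numeric(pi1), S1 = S1,
                 y_mean = as.numeric(y_mean), d = d, E = E,
                 electrode_ids = electrode_ids, meta = meta),
            class = "lds_params")
}

#' @export
print.lds_params <- function(x, ...) {
  cat(sprintf("<lds_params> d=%d latent dims, E=%d electrodes\n", x$d, x$E))
  if (!is.null(x$meta$loglik)) {
    cat(sprintf("  fitted: logLik %.2f after %d EM iterations\n",
                x$meta$loglik, x$meta$n_iter))
  }
  invisible(x)
}

#' @method glance lds_params
#' @export
glance.lds_params <- function(x, ...) {
  tibble::tibble(d = x$d, n_electrodes = x$E,
                 loglik = x$meta$loglik %||% NA_real_,
                 n_iter = x$meta$n_iter %||% NA_integer_,
                 converged = x$meta$converged %||% NA,
                 constrained = x$meta$constrained %||% FALSE)
}

#' @method tidy lds_params
#' @export
tidy.lds_params <- function(x, ...) {
  tidy(eigenmodes(x$M, dt = x$meta$bin_width_s %||% 0.015), ...)
}

centered_spikes <- function(params, spikes) {
  spikes <- as_num_matrix(spikes, "spikes")
  assert_that(ncol(spikes) == params$E,
              sprintf("expected %d electrodes, got %d", params$E, ncol(spikes)))
  sweep(spikes, 2, params$y_mean)
}

#' Kalman (RTS) smoothing under an LDS
#'
#' Runs the forward Kalman filter and backward Rauch-Tung-Striebel smoother
#' and returns the smoothed posterior over latent states, including the
#' per-bin log-likelihood contributions of the prediction-error
#' decomposition. With `steady_state = TRUE`, filter and smoother gains are
#' frozen once the predicted state covariance has converged, which leaves
#' the smoothed means essentially unchanged while making long sessions much
#' cheaper.
#'
#' @param params an [lds_params()] object.
#' @param spikes T x E count matrix.
#' @param steady_state freeze gains after covariance convergence?
#' @param want_covs return the per-bin smoothed covariances and lag-one
#'   covariances? (Disable for long sessions to save memory.)
#' @return An object of class `smoothed_posterior`: `means` (T x d),
#'   `covs` and `lag_covs` (d x d x T arrays, if requested), `ll_bins`,
#'   `loglik`, and the sufficient statistics used by [em_fit()].
#' @export
kalman_smooth <- function(params, spikes, steady_state = FALSE,
                          want_covs = TRUE) {
  yc <- centered_spikes(params, spikes)
  out <- cpp_kalman_smooth(yc, params$M, params$N, params$P, diag(params$R),
                           params$pi1, params$S1, steady_state, 1e-10,
                           want_covs)
  structure(list(means = out$xs, covs = out$Vs, lag_covs = out$Vlag,
                 ll_bins = drop(out$ll_bins), loglik = out$loglik,
                 suffstats = out[c("S_all", "S_head", "S_tail", "S_lag",
                                   "Sys", "x1", "V1")]),
            class = "smoothed_posterior")
}

#' Marginal log-likelihood of spikes under an LDS
#'
#' Exact Gaussian log-likelihood of the observed (mean-centered) counts via
#' the Kalman filter's prediction-error decomposition.
#'
#' @inheritParams kalman_smooth
#' @return A scalar log-likelihood.
#' @export
joint_log_likelihood <- function(params, spikes) {
  yc <- centered_spikes(params, spikes)
  ll <- cpp_kalman_loglik(yc, params$M, params$N, params$P, diag(params$R),
                          params$pi1, params$S1)
  assert_that(is.finite(ll), "log-likelihood is not finite (singular innovation?)")
  ll
}

em_mstep <- function(ss, yc, update_dynamics = TRUE, params = NULL) {
  T_bins <- nrow(yc); d <- length(ss$x1)
  if (update_dynamics) {
    M <- t(solve(ss$S_tail, t(ss$S_lag)))
    Nfull <- (ss$S_head - M %*% t(ss$S_lag)) / (T_bins - 1)
    N <- diag(pmax(diag(Nfull), 1e-10), d)
  } else {
    M <- params$M; N <- params$N
  }
  P <- t(solve(ss$S_all, t(ss$Sys)))
  Rdiag <- (colSums(yc^2) - rowSums(P * ss$Sys)) / T_bins
  R <- diag(pmax(Rdiag, 1e-10), ncol(yc))
  S1 <- (ss$V1 + t(ss$V1)) / 2 + diag(1e-10, d)
  list(M = M, N = N, P = P, R = R, pi1 = drop(ss$x1), S1 = S1)
}

em_loop <- function(spikes, init, opts, update_dynamics = TRUE) {
  opts <- utils::modifyList(list(tol = 1e-6, max_iter = 500,
                                 steady_state = FALSE, verbose = FALSE,
                                 fa_iter = 200), opts %||% list())
  params <- init
  yc <- centered_spikes(params, spikes)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(opts$max_iter)) {
    sm <- cpp_kalman_smooth(yc, params$M, params$N, params$P, diag(params$R),
                            params$pi1, params$S1, opts$steady_state, 1e-10,
                            FALSE)
    ll <- sm$loglik
    if (!is.finite(ll)) {
      abort(paste0("EM log-likelihood became non-finite at iteration ", it,
                   "; trace: ", paste(signif(trace, 8), collapse = ", ")),
            class = "dynbmi_em_error")
    }
    trace <- c(trace, ll)
    if (it > 1) {
      prev <- trace[it - 1]
      if (abs(ll - prev) < opts$tol * (abs(prev) + 1)) { converged <- TRUE }
    }
    up <- em_mstep(sm[c("S_all", "S_head", "S_tail", "S_lag", "Sys", "x1", "V1")],
                   yc, update_dynamics = update_dynamics, params = params)
    params <- lds_params(up$M, up$N, up$P, up$R, up$pi1, up$S1,
                         y_mean = params$y_mean,
                         electrode_ids = params$electrode_ids)
    if (opts$verbose) message(sprintf("EM iter %d: logLik %.4f", it, ll))
    if (converged) break
  }
  final_ll <- cpp_kalman_loglik(yc, params$M, params$N, params$P,
                                diag(params$R), params$pi1, params$S1)
  trace <- c(trace, final_ll)
  params$meta <- list(loglik = final_ll, ll_trace = trace, n_iter = it,
                      converged = converged, constrained = !update_dynamics,
                      steady_state = opts$steady_state)
  params
}

#' Fit the latent LDS by expectation-maximization
#'
#' Maximum-likelihood systems identification of the LDS from spike counts
#' alone. The fit is initialized with factor analysis
#' ([init_factor_analysis()]); the E-step is exact Kalman smoothing (with an
#' optional steady-state gain approximation); the M-step is the closed-form
#' update with `N` and `R` projected to diagonal. The marginal
#' log-likelihood is non-decreasing across iterations and is recorded in
#' `meta$ll_trace`.
#'
#' @param spikes T x E count matrix.
#' @param d latent dimension (default 20).
#' @param opts list of options: `tol` (relative log-likelihood change for
#'   convergence, default 1e-6), `max_iter` (default 500), `steady_state`
#'   (freeze E-step gains after covariance convergence, default FALSE),
#'   `fa_iter`, `verbose`.
#' @param electrode_ids optional electrode labels stored with the fit.
#' @return A fitted [lds_params()] with metadata (`loglik`, `ll_trace`,
#'   `n_iter`, `converged`).
#' @export
em_fit <- function(spikes, d = 20, opts = list(), electrode_ids = NULL) {
  spikes <- as.matrix(spikes)
  if (nrow(spikes) <= 10 * d) {
    warn(sprintf("T = %d is small for d = %d (T > 10 d recommended)",
                 nrow(spikes), d))
  }
  init <- init_factor_analysis(spikes, d,
                               fa_iter = (opts$fa_iter %||% 200))
  init$electrode_ids <- electrode_ids
  em_loop(spikes, init, opts, update_dynamics = TRUE)
}

#' Constrained EM with a remembered dynamics process
#'
#' The hysteresis mechanism: the dynamics process `(M, N)` is fixed to
#' values remembered from a historical dataset, and only the observation
#' process and initial state `(P, R, pi1, S1)` are re-estimated from
#' today's spikes. The returned `M` and `N` are bit-identical to the
#' inputs.
#'
#' @param spikes T x E count matrix.
#' @param M_hyst,N_hyst remembered d x d dynamics and (diagonal) process
#'   covariance.
#' @param opts as in [em_fit()].
#' @param electrode_ids optional electrode labels stored with the fit.
#' @return A fitted [lds_params()] with `meta$constrained = TRUE`.
#' @export
em_fit_constrained <- function(spikes, M_hyst, N_hyst, opts = list(),
                               electrode_ids = NULL) {
  spikes <- as.matrix(spikes)
  M_hyst <- as_num_matrix(M_hyst, "M_hyst")
  N_hyst <- as_num_matrix(N_hyst, "N_hyst")
  d <- nrow(M_hyst)
  assert_that(all(dim(M_hyst) == d) && all(dim(N_hyst) == d),
              "M_hyst and N_hyst must be square with matching dimension")
  init <- init_factor_analysis(spikes, d,
                               fa_iter = (opts$fa_iter %||% 200))
  init$M <- M_hyst
  init$N <- N_hyst
  init$electrode_ids <- electrode_ids
  out <- em_loop(spikes, init, opts, update_dynamics = FALSE)
  out$M <- M_hyst   # bit-identical by construction
  out$N <- N_hyst
  out
}

#' Serialize / restore LDS parameters
#'
#' JSON container holding the parameter matrices, the observation mean and
#' fit metadata. This file is the "remembered dynamics" artifact consumed
#' by HNDF/MNDF training.
#'
#' @param params an [lds_params()].
#' @param path file path.
#' @return `path` (write) or the restored [lds_params()] (read).
#' @export
write_lds <- function(params, path) {
  payload <- list(format = "dynbmi-lds", version = 1L,
                  M = unname(params$M), N_diag = diag(params$N),
                  P = unname(params$P), R_diag = diag(params$R),
                  pi1 = params$pi1, S1 = unname(params$S1),
                  y_mean = params$y_mean,
                  electrode_ids = params$electrode_ids,
                  meta = params$meta[setdiff(names(params$meta), "ll_trace")])
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor", null = "null"),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lds
#' @export
read_lds <- function(path) {
  x <- jsonlite::fromJSON(path)
  assert_that(identical(x$format, "dynbmi-lds"), "not a dynbmi LDS file",
              class = "dynbmi_format_error")
  lds_params(M = x$M, N = diag(x$N_diag, length(x$N_diag)), P = x$P,
             R = diag(x$R_diag, length(x$R_diag)), pi1 = x$pi1, S1 = x$S1,
             y_mean = x$y_mean, electrode_ids = x$electrode_ids,
             meta = as.list(x$meta))
}
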