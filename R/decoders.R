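#' Steady-state Kalman gain of the latent LDS
#'
#' Iterates the Kalman-gain recursion
#' `K = (I + (M Sigma M' + N) P R^-1 P')^-1 (M Sigma M' + N) P R^-1`
#' together with the covariance update until the gain reaches its fixed
#' point. The decoders run this steady-state form: in practice the
#' recursion converges within a few seconds of data.
#'
#' @param params an [lds_params()].
#' @param sigma0 initial state covariance (default `params$S1`).
#' @param tol Frobenius-norm change in `K` declaring convergence
#'   (default 1e-12, comfortably below the 1e-9 fixed-point contract).
#' @param max_iter iteration cap (default 50000).
#' @return List with `K` (d x E steady-state gain), `sigma` (converged
#'   filtered covariance), `sigma_pred` (predicted covariance), `n_iter`.
#' @export
steady_state_gain <- function(params, sigma0 = NULL, tol = 1e-12,
                              max_iter = 50000) {
  M <- params$M; N <- params$N; P <- params$P
  Rinv <- 1 / diag(params$R)
  PtRi <- t(P) * rep(Rinv, each = ncol(P))      # P' R^-1, d x E
  Sigma <- sigma0 %||% params$S1
  d <- nrow(M)
  K_prev <- matrix(Inf, d, nrow(P))
  for (i in seq_len(max_iter)) {
    Sp <- M %*% Sigma %*% t(M) + N
    K <- solve(diag(d) + Sp %*% PtRi %*% P, Sp %*% PtRi)
    if (!all(is.finite(K))) {
      abort("steady-state gain recursion diverged", class = "dynbmi_error")
    }
    delta <- sqrt(sum((K - K_prev)^2))
    Sigma <- (diag(d) - K %*% P) %*% Sp
    Sigma <- (Sigma + t(Sigma)) / 2
    if (delta < tol) {
      return(list(K = K, sigma = Sigma, sigma_pred = Sp, n_iter = i))
    }
    K_prev <- K
  }
  abort(sprintf("steady-state gain did not converge in %d iterations", max_iter),
        class = "dynbmi_error")
}

#' Infer latent neural states with the steady-state filter
#'
#' Runs `s_k = M s_{k-1} + K (y_k - P M s_{k-1})` with the cached
#' steady-state gain, starting from `s_0 = pi1`.
#'
#' @param decoder a `bmi_decoder` of a dynamical kind, or an
#'   [lds_params()] (the gain is then computed on the fly).
#' @param spikes T x E counts matching the decoder's electrode set.
#' @return T x d matrix of inferred states.
#' @export
infer_states <- function(decoder, spikes) {
  if (inherits(decoder, "bmi_decoder")) {
    params <- decoder$lds; K <- decoder$K
    assert_that(!is.null(params), "decoder has no latent dynamical system")
  } else {
    params <- decoder
    K <- steady_state_gain(params)$K
  }
  yc <- centered_spikes(params, spikes)
  cpp_ss_filter(yc, params$M, K, params$P, params$pi1)
}

#' Least-squares kinematic readout from latent states
#'
#' Finds `L_s` minimizing `||X - L_s [S; 1]||^2` (a row of ones is appended
#' so a bias is learned) via the normal equations.
#'
#' @param states T x d latent states.
#' @param kinematics T x 4 kinematics `px, py, vx, vy`.
#' @param alpha position/velocity blend weight stored with the readout
#'   (default 0.975).
#' @param dt bin width in seconds.
#' @param ridge optional ridge penalty for rank-deficient designs; by
#'   default rank deficiency is an error.
#' @return A `neural_readout`: `L_s` (4 x (d+1), bias last column),
#'   `alpha`, `dt`.
#' @export
fit_readout <- function(states, kinematics, alpha = 0.975, dt = 0.015,
                        ridge = NULL) {
  S <- as_num_matrix(states, "states")
  X <- as_num_matrix(kinematics, "kinematics")
  assert_that(nrow(S) == nrow(X), "states and kinematics must share rows")
  assert_that(nrow(S) > ncol(S) + 1, "need T > d + 1 to fit the readout")
  Sb <- cbind(S, 1)
  G <- crossprod(Sb)
  if (is.null(ridge)) {
    if (rcond(G) < 1e-12) {
      abort("rank-deficient readout design (supply `ridge` to regularize)",
            class = "dynbmi_rank_error")
    }
  } else {
    G <- G + diag(ridge, ncol(Sb))
  }
  L <- t(solve(G, crossprod(Sb, X)))
  structure(list(L_s = L, alpha = alpha, dt = dt, ridged = !is.null(ridge)),
            class = "neural_readout")
}

#' Blend decoded position with integrated velocity
#'
#' `p_k = (1 - alpha) p_hat + alpha (p_prev + v_prev dt)`: the displayed
#' cursor position takes a small contribution (2.5% by default) from the
#' directly decoded position and the rest from integrating decoded
#' velocity, which stabilizes the cursor in the workspace.
#'
#' @param p_hat decoded position (2-vector, cm).
#' @param p_prev previous displayed position (cm).
#' @param v_prev previous decoded velocity (cm/s).
#' @param alpha blend weight in `[0, 1]` (default 0.975).
#' @param dt bin width (s).
#' @return Blended 2-vector position (cm).
#' @export
blend_position <- function(p_hat, p_prev, v_prev, alpha = 0.975, dt = 0.015) {
  assert_that(all(is.finite(c(p_hat, p_prev, v_prev, alpha, dt))),
              "blend_position requires finite inputs")
  assert_that(alpha >= 0 && alpha <= 1, "alpha must be in [0, 1]")
  (1 - alpha) * p_hat + alpha * (p_prev + v_prev * dt)
}

new_decoder <- function(kind, session, ...) {
  structure(c(list(kind = kind, electrode_ids = session$electrode_ids,
                   bin_width_s = session$bin_width_s), list(...)),
            class = "bmi_decoder")
}

#' @export
print.bmi_decoder <- function(x, ...) {
  cat(sprintf("<bmi_decoder> %s, %d electrodes\n", toupper(x$kind),
              length(x$electrode_ids)))
  invisible(x)
}

#' @method glance bmi_decoder
#' @export
glance.bmi_decoder <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_electrodes = length(x$electrode_ids),
                 d = if (!is.null(x$lds)) x$lds$d else NA_integer_,
                 loglik = if (!is.null(x$lds)) x$lds$meta$loglik %||% NA_real_ else NA_real_)
}

train_bins <- function(session, split) {
  tr <- session$trials[session$trials$trial_id %in% split$train_trial_ids, ]
  trial_bins(tr)
}

finish_dynamical_decoder <- function(kind, session, split, lds) {
  idx <- train_bins(session, split)
  K <- steady_state_gain(lds)$K
  dec <- new_decoder(kind, session, lds = lds, K = K, readout = NULL)
  states <- infer_states(dec, session$spikes[idx, , drop = FALSE])
  dec$readout <- fit_readout(states, session$kinematics[idx, , drop = FALSE],
                             dt = session$bin_width_s)
  dec
}

#' Train a neural dynamical filter (NDF)
#'
#' Fits the latent LDS to the training-block spikes by EM
#' ([em_fit()]), infers training states with the steady-state Kalman
#' filter, and fits the linear kinematic readout with bias.
#'
#' @param session a [bmi_session()].
#' @param split a [split_train_test()] result.
#' @param d latent dimension (default 20).
#' @param opts EM options, see [em_fit()].
#' @return A `bmi_decoder` of kind `"ndf"`.
#' @export
train_ndf <- function(session, split, d = 20, opts = list()) {
  idx <- train_bins(session, split)
  lds <- em_fit(session$spikes[idx, , drop = FALSE], d = d, opts = opts,
                electrode_ids = session$electrode_ids)
  finish_dynamical_decoder("ndf", session, split, lds)
}

#' Train a hysteresis (HNDF) or memory (MNDF) neural dynamical filter
#'
#' Both variants remember the dynamics process `(M, N)` learned from a
#' historical dataset when more electrodes were available. The HNDF
#' re-estimates the observation process on today's spikes with the
#' constrained EM ([em_fit_constrained()]); the MNDF additionally reuses
#' the remembered observation process restricted to the surviving
#' electrodes (requiring known electrode identities) and needs no EM.
#' In both cases a fresh kinematic readout is fit for the surviving
#' electrodes.
#'
#' @param session today's [bmi_session()] (possibly with electrodes lost).
#' @param split a [split_train_test()] result.
#' @param remembered the historical [lds_params()].
#' @param mode `"hndf"` or `"mndf"`.
#' @param opts EM options (HNDF only).
#' @return A `bmi_decoder` of kind `"hndf"` or `"mndf"`.
#' @export
train_hysteresis <- function(session, split, remembered,
                             mode = c("hndf", "mndf"), opts = list()) {
  mode <- match.arg(mode)
  idx <- train_bins(session, split)
  if (mode == "hndf") {
    lds <- em_fit_constrained(session$spikes[idx, , drop = FALSE],
                              M_hyst = remembered$M, N_hyst = remembered$N,
                              opts = opts,
                              electrode_ids = session$electrode_ids)
  } else {
    assert_that(!is.null(remembered$electrode_ids),
                "MNDF requires a remembered LDS with known electrode identities")
    pos <- match(session$electrode_ids, remembered$electrode_ids)
    assert_that(!anyNA(pos),
                "MNDF requires every surviving electrode to exist in the remembered set")
    lds <- lds_params(M = remembered$M, N = remembered$N,
                      P = remembered$P[pos, , drop = FALSE],
                      R = diag(diag(remembered$R)[pos], length(pos)),
                      pi1 = remembered$pi1, S1 = remembered$S1,
                      y_mean = remembered$y_mean[pos],
                      electrode_ids = session$electrode_ids,
                      meta = list(constrained = TRUE, source = "mndf"))
  }
  finish_dynamical_decoder(mode, session, split, lds)
}

#' Intention-estimation transform of training kinematics
#'
#' Implements the assumption that the subject always intends to move
#' straight to the prompted target and to stop inside it: every velocity
#' during a trial is rotated (magnitude preserved) to point at the target,
#' and velocities at bins where the cursor is inside the target's square
#' acceptance window are set to zero. Zero velocities outside the window
#' are left unchanged, as rotation is undefined for them. A bias row of
#' ones is appended.
#'
#' @param kinematics T x 4 matrix `px, py, vx, vy`.
#' @param trials trial table (see [bmi_session()]).
#' @param acceptance_window_cm side of the square acceptance window
#'   centered on the target (default 4); containment is closed
#'   (`|dx| <= w/2` and `|dy| <= w/2`).
#' @return T x 5 matrix `px, py, vx, vy, 1` of intention kinematics.
#' @export
intention_transform <- function(kinematics, trials, acceptance_window_cm = 4) {
  X <- as_num_matrix(kinematics, "kinematics")
  out <- cbind(X, 1)
  half <- acceptance_window_cm / 2
  for (i in seq_len(nrow(trials))) {
    rows <- seq.int(trials$start_bin[i] + 1L, trials$end_bin[i])
    tgt <- c(trials$target_x_cm[i], trials$target_y_cm[i])
    p <- X[rows, 1:2, drop = FALSE]
    v <- X[rows, 3:4, drop = FALSE]
    inside <- abs(p[, 1] - tgt[1]) <= half & abs(p[, 2] - tgt[2]) <= half
    to_tgt <- cbind(tgt[1] - p[, 1], tgt[2] - p[, 2])
    dn <- sqrt(rowSums(to_tgt^2))
    speed <- sqrt(rowSums(v^2))
    rot <- !inside & speed > 0 & dn > 0
    v[rot, ] <- to_tgt[rot, , drop = FALSE] / dn[rot] * speed[rot]
    v[inside, ] <- 0
    out[rows, 3:4] <- v
  }
  out
}

# closed-form maximum-likelihood estimates of the kinematic-state system:
# X is the 5 x K (altered) kinematic sequence, Y the E x K spike sequence
fitkf_ml_estimates <- function(X, Y) {
  K_bins <- ncol(X)
  X1 <- X[, -K_bins, drop = FALSE]
  X2 <- X[, -1, drop = FALSE]
  G <- X1 %*% t(X1)
  assert_that(rcond(G) > 1e-14, "singular kinematic Gram matrix",
              class = "dynbmi_rank_error")
  A <- X2 %*% t(X1) %*% solve(G)
  W <- (X2 - A %*% X1) %*% t(X2 - A %*% X1) / (K_bins - 1)
  Gx <- X %*% t(X)
  assert_that(rcond(Gx) > 1e-14, "singular kinematic Gram matrix",
              class = "dynbmi_rank_error")
  C <- Y %*% t(X) %*% solve(Gx)
  Q <- (Y - C %*% X) %*% t(Y - C %*% X) / K_bins
  list(A = A, W = W, C = C, Q = Q)
}

# generic Riccati fixed point for a full observation covariance (FIT-KF)
riccati_gain_full <- function(A, W, C, Q, tol = 1e-11, max_iter = 50000) {
  d <- nrow(A)
  Sigma <- W
  K_prev <- matrix(Inf, d, nrow(C))
  for (i in seq_len(max_iter)) {
    Sp <- A %*% Sigma %*% t(A) + W
    S <- C %*% Sp %*% t(C) + Q
    K <- t(solve(S, C %*% Sp))
    Sigma <- (diag(d) - K %*% C) %*% Sp
    Sigma <- (Sigma + t(Sigma)) / 2
    if (sqrt(sum((K - K_prev)^2)) < tol) return(list(K = K, sigma = Sigma))
    K_prev <- K
  }
  abort("FIT-KF Riccati recursion did not converge", class = "dynbmi_error")
}

#' Train a feedback-intention trained Kalman filter (FIT-KF)
#'
#' A kinematic-state Kalman filter on `(px, py, vx, vy, 1)`. With
#' `intention_estimation = TRUE` the training kinematics are first passed
#' through [intention_transform()]; with it off, this is the plain
#' position/velocity Kalman filter. All four system matrices are the
#' closed-form maximum-likelihood estimates:
#' `A` and `W` from the lag-one regression of the (altered) kinematics,
#' `C` and `Q` from the regression of spikes on kinematics.
#'
#' @param session a [bmi_session()].
#' @param split a [split_train_test()] result.
#' @param intention_estimation apply intention estimation? (default TRUE)
#' @param acceptance_window_cm target window used by the transform.
#' @return A `bmi_decoder` of kind `"fitkf"` (or `"fitkf_plain"`).
#' @export
train_fitkf <- function(session, split, intention_estimation = TRUE,
                        acceptance_window_cm = 4) {
  idx <- train_bins(session, split)
  tr <- session$trials[session$trials$trial_id %in% split$train_trial_ids, ]
  if (intention_estimation) {
    Xt <- intention_transform(session$kinematics, session$trials,
                              acceptance_window_cm)[idx, , drop = FALSE]
  } else {
    Xt <- cbind(session$kinematics, 1)[idx, , drop = FALSE]
  }
  Y <- t(session$spikes[idx, , drop = FALSE])      # E x K
  X <- t(Xt)                                       # 5 x K
  est <- fitkf_ml_estimates(X, Y)
  A <- est$A; W <- est$W; C <- est$C; Q <- est$Q
  # the bias state is deterministic: clamp its dynamics exactly
  A[5, ] <- c(0, 0, 0, 0, 1)
  W[5, ] <- 0; W[, 5] <- 0
  g <- riccati_gain_full(A, W, C, Q)
  new_decoder(if (intention_estimation) "fitkf" else "fitkf_plain", session,
              fitkf = list(A = A, W = W, C = C, Q = Q, K = g$K,
                           intention_estimation = intention_estimation,
                           acceptance_window_cm = acceptance_window_cm))
}

#' Causal Gaussian smoothing kernel
#'
#' Weights over present and past bins, proportional to a Gaussian of the
#' given standard deviation truncated at 4 sigma, normalized to sum to one.
#' Strictly future bins get zero weight.
#'
#' @param sigma_s kernel standard deviation in seconds (default 0.100).
#' @param dt bin width in seconds.
#' @return Numeric vector of weights for lags `0, 1, 2, ...` bins.
#' @export
ole_kernel <- function(sigma_s = 0.1, dt = 0.015) {
  lags <- 0:ceiling(4 * sigma_s / dt)
  w <- exp(-(lags * dt)^2 / (2 * sigma_s^2))
  w / sum(w)
}

smooth_causal <- function(Y, w) {
  T_bins <- nrow(Y)
  out <- matrix(0, T_bins, ncol(Y))
  L <- length(w)
  for (j in seq_len(L)) {
    lag <- j - 1L
    rows <- seq.int(lag + 1L, T_bins)
    out[rows, ] <- out[rows, ] + w[j] * Y[rows - lag, , drop = FALSE]
  }
  # renormalize the ramp-in where part of the kernel precedes the recording
  cw <- cumsum(w)
  head_n <- min(L - 1L, T_bins)
  if (head_n > 0) {
    out[seq_len(head_n), ] <- out[seq_len(head_n), , drop = FALSE] /
      cw[seq_len(head_n)]
  }
  out
}

#' Train an optimal linear estimator (OLE)
#'
#' Convolves each channel with a causal Gaussian kernel (100 ms s.d.) and
#' solves the least-squares regression from smoothed counts (plus bias) to
#' kinematics.
#'
#' @param session a [bmi_session()].
#' @param split a [split_train_test()] result.
#' @param kernel_sigma_s smoothing kernel s.d. in seconds (default 0.100).
#' @param ridge optional ridge penalty for rank-deficient designs.
#' @return A `bmi_decoder` of kind `"ole"`.
#' @export
train_ole <- function(session, split, kernel_sigma_s = 0.1, ridge = NULL) {
  w <- ole_kernel(kernel_sigma_s, session$bin_width_s)
  Ys <- smooth_causal(session$spikes, w)
  idx <- train_bins(session, split)
  Yb <- cbind(Ys[idx, , drop = FALSE], 1)
  G <- crossprod(Yb)
  if (is.null(ridge)) {
    assert_that(rcond(G) > 1e-14, "rank-deficient OLE design",
                class = "dynbmi_rank_error")
  } else {
    G <- G + diag(ridge, ncol(Yb))
  }
  L_y <- t(solve(G, crossprod(Yb, session$kinematics[idx, , drop = FALSE])))
  new_decoder("ole", session,
              ole = list(L_y = L_y, kernel = w, kernel_sigma_s = kernel_sigma_s))
}

#' Decode kinematics offline
#'
#' Runs the decoder over the bins of the requested trials (states carry
#' across trial boundaries; the displayed position is reset to the true
#' hand position at the first bin of every trial so position error does
#' not accumulate across trials). For the dynamical decoders the displayed
#' position follows the position/velocity blend ([blend_position()]); the
#' FIT-KF position comes from its own kinematic state; OLE positions are
#' integrated from decoded velocity.
#'
#' @param decoder a trained `bmi_decoder`.
#' @param session the [bmi_session()] to decode.
#' @param trial_ids trials to decode (default: all).
#' @return A tibble with columns `bin` (1-based global bin), `trial_id`,
#'   `px, py, vx, vy` (decoded), of class `decoded_kinematics`.
#' @export
decode_offline <- function(decoder, session, trial_ids = NULL) {
  assert_that(identical(decoder$electrode_ids, session$electrode_ids),
              paste0("electrode mismatch: decoder expects [",
                     paste(utils::head(decoder$electrode_ids, 4), collapse = ", "),
                     ", ...]"))
  trial_ids <- trial_ids %||% session$trials$trial_id
  tr <- session$trials[session$trials$trial_id %in% trial_ids, , drop = FALSE]
  bins <- trial_bins(tr)
  Y <- session$spikes[bins, , drop = FALSE]
  dt <- session$bin_width_s
  T_loc <- length(bins)
  starts_loc <- cumsum(c(1L, utils::head(tr$end_bin - tr$start_bin, -1)))
  trial_of_bin <- rep(tr$trial_id, tr$end_bin - tr$start_bin)
  true_pos <- session$kinematics[bins, 1:2, drop = FALSE]

  if (decoder$kind %in% c("ndf", "hndf", "mndf")) {
    S <- infer_states(decoder, Y)
    L <- decoder$readout$L_s
    Sb <- cbind(S, 1)
    p_hat <- Sb %*% t(L[1:2, , drop = FALSE])
    v_hat <- Sb %*% t(L[3:4, , drop = FALSE])
    pos <- matrix(0, T_loc, 2)
    alpha <- decoder$readout$alpha
    for (k in seq_len(T_loc)) {
      if (k %in% starts_loc) {
        pos[k, ] <- true_pos[k, ]
      } else {
        pos[k, ] <- blend_position(p_hat[k, ], pos[k - 1, ], v_hat[k - 1, ],
                                   alpha, dt)
      }
    }
    out <- cbind(pos, v_hat)
  } else if (decoder$kind %in% c("fitkf", "fitkf_plain")) {
    fk <- decoder$fitkf
    x <- c(true_pos[1, ], 0, 0, 1)
    out <- matrix(0, T_loc, 4)
    AM <- fk$A; K <- fk$K; C <- fk$C
    for (k in seq_len(T_loc)) {
      if (k %in% starts_loc) x[1:2] <- true_pos[k, ]
      xp <- AM %*% x
      x <- drop(xp + K %*% (Y[k, ] - C %*% xp))
      x[5] <- 1
      if (k %in% starts_loc) x[1:2] <- true_pos[k, ]
      out[k, ] <- x[1:4]
    }
  } else if (decoder$kind == "ole") {
    Ys <- smooth_causal(Y, decoder$ole$kernel)
    Xd <- cbind(Ys, 1) %*% t(decoder$ole$L_y)
    v_hat <- Xd[, 3:4, drop = FALSE]
    pos <- matrix(0, T_loc, 2)
    for (k in seq_len(T_loc)) {
      pos[k, ] <- if (k %in% starts_loc) true_pos[k, ]
        else pos[k - 1, ] + v_hat[k, ] * dt
    }
    out <- cbind(pos, v_hat)
  } else {
    abort(paste0("unknown decoder kind: ", decoder$kind))
  }
  res <- tibble::tibble(bin = bins, trial_id = trial_of_bin,
                        px = out[, 1], py = out[, 2],
                        vx = out[, 3], vy = out[, 4])
  class(res) <- c("decoded_kinematics", class(res))
  attr(res, "kind") <- decoder$kind
  res
}
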