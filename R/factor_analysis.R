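# Factor analysis by EM (PCA warm start), used to initialize the LDS.
# Model: y = mu + Lambda z + eps, eps ~ N(0, Psi) with Psi diagonal.
# All updates work on the E x E sample covariance, so the cost is
# independent of T after the covariance is formed.

fa_em <- function(Y, d, n_iter = 200, tol = 1e-8) {
  Y <- as_num_matrix(Y, "Y")
  T_bins <- nrow(Y); E <- ncol(Y)
  assert_that(T_bins > d && E >= d, "need T > d and E >= d for factor analysis")
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  C <- crossprod(Yc) / T_bins
  v <- diag(C)
  zero_var <- which(v <= .Machine$double.eps * 100)
  if (length(zero_var)) {
    abort(paste0("zero-variance electrode(s): ",
                 paste(zero_var, collapse = ", ")),
          class = "dynbmi_degenerate_error")
  }

  # PCA warm start
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(d)], 1e-8)
  resid <- if (E > d) mean(eg$values[(d + 1):E]) else 1e-4
  Lambda <- eg$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(ev - resid, 1e-8)), d)
  Psi <- pmax(v - rowSums(Lambda^2), 1e-6)

  ll_old <- -Inf
  for (it in seq_len(n_iter)) {
    # beta = Lambda' (Lambda Lambda' + Psi)^-1 via Woodbury (Psi diagonal)
    LtPi <- t(Lambda) / rep(Psi, each = d)          # d x E
    G <- solve(diag(d) + LtPi %*% Lambda)           # (I + L'Psi^-1 L)^-1
    beta <- G %*% LtPi                              # d x E
    CbT <- C %*% t(beta)                            # E x d
    Ezz <- G + beta %*% CbT                         # E[zz'] under model
    Lambda <- CbT %*% solve(Ezz)
    Psi <- pmax(diag(C) - rowSums(Lambda * CbT), 1e-8)

    # marginal log-likelihood of the Gaussian model (per fit, up to const)
    LtPi <- t(Lambda) / rep(Psi, each = d)
    A <- diag(d) + LtPi %*% Lambda
    logdetS <- sum(log(Psi)) + determinant(A, logarithm = TRUE)$modulus
    Sinv_C_tr <- sum(diag(C) / Psi) -
      sum((solve(A) %*% LtPi) * (LtPi %*% C))
    ll <- -0.5 * T_bins * (E * log(2 * pi) + logdetS + Sinv_C_tr)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }

  LtPi <- t(Lambda) / rep(Psi, each = d)
  beta <- solve(diag(d) + LtPi %*% Lambda) %*% LtPi
  scores <- Yc %*% t(beta)
  list(loadings = Lambda, uniqueness = Psi, mean = mu, scores = scores,
       loglik = ll_old, n_iter = it)
}

#' Initialize LDS parameters by factor analysis
#'
#' Fits factor analysis to the spike counts (EM with a PCA warm start),
#' takes the loadings and uniquenesses as the initial observation process
#' `(P, R)`, infers factor scores, and sets the initial state statistics
#' from them: `pi1` is the score mean, `S1` and `N` the (diagonalized)
#' score covariance, and `M` the maximum-likelihood matrix mapping the
#' scores forward one time step.
#'
#' @param spikes T x E count matrix.
#' @param d latent dimension.
#' @param fa_iter factor-analysis EM iterations (default 200).
#' @return An [lds_params()] object (with the observation mean stored).
#' @export
init_factor_analysis <- function(spikes, d, fa_iter = 200) {
  fa <- fa_em(spikes, d, n_iter = fa_iter)
  Z <- fa$scores
  T_bins <- nrow(Z)
  Z1 <- Z[-T_bins, , drop = FALSE]
  Z2 <- Z[-1, , drop = FALSE]
  M <- t(solve(crossprod(Z1), crossprod(Z1, Z2)))
  Sz <- crossprod(sweep(Z, 2, colMeans(Z))) / T_bins
  lds_params(M = M,
             N = diag(pmax(diag(Sz), 1e-8), d),
             P = fa$loadings,
             R = diag(pmax(fa$uniqueness, 1e-8), length(fa$uniqueness)),
             pi1 = colMeans(Z),
             S1 = Sz + diag(1e-10, d),
             y_mean = fa$mean)
}
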