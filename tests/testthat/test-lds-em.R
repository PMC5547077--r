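# Systems identification: factor-analysis initialization, Kalman smoothing,
# EM, constrained EM, and the marginal log-likelihood.

test_that("factor analysis recovers the observation subspace in the small-noise limit", {
  withr::local_seed(1)
  d <- 3; E <- 12; T_bins <- 3000
  P_true <- qr.Q(qr(matrix(rnorm(E * d), E, d))) * 5
  Z <- matrix(rnorm(T_bins * d), T_bins, d)
  Y <- Z %*% t(P_true) + matrix(rnorm(T_bins * E, sd = 1e-4), T_bins, E)
  init <- init_factor_analysis(Y, d)
  # principal angles between the spans of P_true and fitted loadings
  qa <- qr.Q(qr(P_true)); qb <- qr.Q(qr(init$P))
  angles <- acos(pmin(svd(crossprod(qa, qb))$d, 1))
  expect_lt(max(angles), 1e-3)
})

test_that("white-noise observations give near-zero initial dynamics", {
  withr::local_seed(2)
  Y <- matrix(rnorm(20000 * 6), 20000, 6)
  init <- init_factor_analysis(Y, 2)
  expect_lt(norm(init$M, "2"), 0.1)
  # oracle: direct lag-one regression of independent scores is also ~0
})

test_that("a constant electrode is rejected with its index", {
  withr::local_seed(3)
  Y <- matrix(rpois(500 * 4, 1), 500, 4)
  Y[, 3] <- 2
  expect_error(init_factor_analysis(Y, 2), "3",
               class = "dynbmi_degenerate_error")
})

test_that("smoothed means match the pseudo-inverse projection when noise vanishes", {
  withr::local_seed(4)
  d <- 3; E <- 6
  P <- matrix(rnorm(E * d), E, d)
  params <- lds_params(M = diag(0.9, d), N = diag(0.1, d), P = P,
                       R = diag(1e-12, E), pi1 = rep(0, d), S1 = diag(1, d))
  S_true <- matrix(rnorm(50 * d), 50, d)
  Y <- S_true %*% t(P)
  sm <- kalman_smooth(params, Y)
  proj <- Y %*% t(MASS::ginv(P))
  expect_lt(max(abs(sm$means - proj)), 1e-6)
})

test_that("steady-state smoothing agrees with the exact smoother after burn-in", {
  cfg <- small_config(n_trials = 120)
  s <- small_session(cfg)
  T_use <- 5000
  stopifnot(nrow(s$spikes) >= T_use)
  Y <- s$spikes[seq_len(T_use), ]
  p <- init_factor_analysis(Y, 4)
  full <- kalman_smooth(p, Y, steady_state = FALSE)
  ss <- kalman_smooth(p, Y, steady_state = TRUE)
  expect_lt(max(abs(full$means[101:T_use, ] - ss$means[101:T_use, ])), 1e-6)
})

test_that("a single bin reduces to the Bayes update of the prior", {
  withr::local_seed(5)
  d <- 2; E <- 3
  P <- matrix(rnorm(E * d), E, d)
  pi1 <- c(0.5, -1); S1 <- diag(c(2, 0.5))
  Rd <- c(0.3, 0.4, 0.5)
  params <- lds_params(M = diag(0.9, d), N = diag(0.2, d), P = P,
                       R = diag(Rd, E), pi1 = pi1, S1 = S1)
  y1 <- matrix(c(1, 2, 3), 1, E)
  sm <- kalman_smooth(params, y1)
  V_post <- solve(solve(S1) + t(P) %*% diag(1 / Rd) %*% P)
  m_post <- V_post %*% (solve(S1, pi1) + t(P) %*% (drop(y1) / Rd))
  expect_equal(drop(sm$means), drop(m_post), tolerance = 1e-10)
  expect_equal(sm$suffstats$V1, V_post, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the marginal log-likelihood matches a hand-computed two-step Gaussian", {
  m <- 0.8; n <- 0.3; p <- 1.2; r <- 0.5; pi1 <- 0.2; s1 <- 0.7
  params <- lds_params(M = matrix(m), N = matrix(n), P = matrix(p),
                       R = matrix(r), pi1 = pi1, S1 = matrix(s1))
  y <- c(0.9, -0.4)
  # closed form: y is bivariate normal with mean p*(pi1, m*pi1) and
  # covariance from the state recursion
  mu <- p * c(pi1, m * pi1)
  v11 <- p^2 * s1 + r
  v22 <- p^2 * (m^2 * s1 + n) + r
  v12 <- p^2 * m * s1
  S <- matrix(c(v11, v12, v12, v22), 2, 2)
  ll_closed <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(t(y - mu) %*% solve(S, y - mu))
  expect_equal(joint_log_likelihood(params, matrix(y, 2, 1)), ll_closed,
               tolerance = 1e-10)
})

test_that("inflating R lowers the log-likelihood density of pure noise as the normalizer dictates", {
  withr::local_seed(6)
  E <- 4; T_bins <- 200
  Y <- matrix(rnorm(T_bins * E, sd = 0.1), T_bins, E)
  base <- lds_params(M = diag(0.5, 2), N = diag(0.1, 2),
                     P = matrix(0.001, E, 2), R = diag(1, E),
                     pi1 = rep(0, 2), S1 = diag(0.1, 2))
  big <- base; big$R <- diag(10, E)
  ll1 <- joint_log_likelihood(base, Y)
  ll2 <- joint_log_likelihood(big, Y)
  # with negligible signal, scaling R by c changes LL by about
  # -T*E/2 * log(c) + (1 - 1/c) * quad/2; the dominant log-normalizer term:
  expect_lt(ll2, ll1)
  expect_lt(abs((ll1 - ll2) - (T_bins * E / 2 * log(10) -
                                 (1 - 1 / 10) * sum(Y^2) / 2)) /
              abs(ll1 - ll2), 0.05)
})

test_that("the log-likelihood is invariant to similarity transforms of the LDS", {
  withr::local_seed(7)
  d <- 3; E <- 5
  cfg <- synth_config(n_electrodes = E, latent_dim = d, n_drive_dims = 0,
                      rotation_frequencies_hz = 1.5, seed = 7)
  tr <- make_ground_truth(cfg)
  sim <- simulate_lds(tr, 300, seed = 7)
  params <- lds_params(M = tr$M, N = tr$N, P = tr$P, R = tr$R,
                       pi1 = rep(0, d), S1 = diag(1, d),
                       y_mean = tr$baseline)
  Tm <- matrix(rnorm(d * d), d, d) + diag(d)
  # N and S1 must stay valid (diagonal/PSD): use an orthogonal transform
  # scaled isotropically so TNT' stays diagonal only if N is isotropic
  params_iso <- params; params_iso$N <- diag(mean(diag(tr$N)), d)
  Q <- qr.Q(qr(Tm))
  p2 <- params_iso
  p2$M <- Q %*% params_iso$M %*% t(Q)
  p2$P <- params_iso$P %*% t(Q)
  p2$N <- params_iso$N                  # isotropic: T N T' = N exactly
  p2$pi1 <- drop(Q %*% params_iso$pi1)
  p2$S1 <- Q %*% params_iso$S1 %*% t(Q)
  ll1 <- joint_log_likelihood(params_iso, sim$y)
  ll2 <- joint_log_likelihood(p2, sim$y)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("EM increases the likelihood monotonically and recovers eigenvalues", {
  cfg <- synth_config(n_electrodes = 24, latent_dim = 4, n_drive_dims = 0,
                      rotation_frequencies_hz = c(1.5, 2.5), seed = 31)
  tr <- make_ground_truth(cfg)
  sim <- simulate_lds(tr, 15000, seed = 31)
  fit <- em_fit(sim$y, d = 4, opts = list(max_iter = 100))
  expect_true(ll_monotone(fit$meta$ll_trace))
  expect_lt(eig_rel_err(fit$M, tr$M), 0.05)
})

test_that("starting EM at the truth does not decrease the likelihood", {
  cfg <- synth_config(n_electrodes = 12, latent_dim = 4, n_drive_dims = 0,
                      rotation_frequencies_hz = 2, seed = 17)
  tr <- make_ground_truth(cfg)
  sim <- simulate_lds(tr, 4000, seed = 17)
  truth_params <- lds_params(M = tr$M, N = tr$N, P = tr$P, R = tr$R,
                             pi1 = rep(0, 4), S1 = diag(1, 4),
                             y_mean = tr$baseline)
  ll0 <- joint_log_likelihood(truth_params, sim$y)
  sm <- kalman_smooth(truth_params, sim$y, want_covs = FALSE)
  up <- dynbmi:::em_mstep(sm$suffstats,
                          dynbmi:::centered_spikes(truth_params, sim$y),
                          update_dynamics = TRUE)
  p1 <- lds_params(up$M, up$N, up$P, up$R, up$pi1, up$S1,
                   y_mean = truth_params$y_mean)
  expect_gte(joint_log_likelihood(p1, sim$y), ll0 - 1e-6 * abs(ll0))
})

test_that("a scalar LDS fit reproduces the empirical second moments", {
  cfg <- synth_config(n_electrodes = 1, latent_dim = 1, n_drive_dims = 0,
                      rotation_frequencies_hz = numeric(0),
                      decay_time_constants_s = 0.12, seed = 23)
  tr <- make_ground_truth(cfg)
  sim <- simulate_lds(tr, 60000, seed = 23)
  fit <- em_fit(sim$y, d = 1, opts = list(max_iter = 300))
  m <- drop(fit$M); p <- drop(fit$P); n <- drop(fit$N); r <- drop(fit$R)
  # implied stationary moments of y vs empirical (model is product-identified)
  s_var <- n / (1 - m^2)
  y_var_model <- p^2 * s_var + r
  y_ac1_model <- p^2 * m * s_var / y_var_model
  yc <- drop(sim$y) - mean(sim$y)
  y_var_emp <- mean(yc^2)
  y_ac1_emp <- mean(yc[-1] * yc[-length(yc)]) / y_var_emp
  expect_lt(abs(y_var_model - y_var_emp) / y_var_emp, 0.02)
  expect_lt(abs(y_ac1_model - y_ac1_emp) / abs(y_ac1_emp), 0.02)
})

test_that("constrained EM leaves the remembered dynamics untouched and stays below the unconstrained optimum", {
  cfg <- synth_config(n_electrodes = 16, latent_dim = 4, n_drive_dims = 0,
                      rotation_frequencies_hz = c(1, 2), seed = 41)
  tr <- make_ground_truth(cfg)
  sim <- simulate_lds(tr, 8000, counts = TRUE, seed = 41)
  con <- em_fit_constrained(sim$y, M_hyst = tr$M, N_hyst = tr$N,
                            opts = list(max_iter = 150))
  expect_identical(con$M, tr$M)
  expect_identical(con$N, tr$N)
  expect_true(ll_monotone(con$meta$ll_trace))
  un <- em_fit(sim$y, d = 4, opts = list(max_iter = 300, tol = 1e-9))
  expect_lte(con$meta$loglik, un$meta$loglik + 1e-6 * abs(un$meta$loglik))
})

test_that("constrained EM with the true dynamics recovers the observation subspace", {
  cfg <- synth_config(n_electrodes = 24, latent_dim = 4, n_drive_dims = 0,
                      rotation_frequencies_hz = c(1.5, 2.5), seed = 43)
  tr <- make_ground_truth(cfg)
  sim <- simulate_lds(tr, 40000, seed = 43)
  con <- em_fit_constrained(sim$y, M_hyst = tr$M, N_hyst = tr$N,
                            opts = list(max_iter = 200, steady_state = TRUE))
  qa <- qr.Q(qr(tr$P)); qb <- qr.Q(qr(con$P))
  angles <- acos(pmin(svd(crossprod(qa, qb))$d, 1))
  expect_lt(max(angles), 0.05)
})

test_that("constrained and unconstrained EM share the E-step: constraining to the unconstrained M-step output reproduces it", {
  cfg <- small_config()
  s <- small_session(cfg)
  Y <- s$spikes[1:2000, ]
  init <- init_factor_analysis(Y, 4)
  yc <- dynbmi:::centered_spikes(init, Y)
  sm <- kalman_smooth(init, Y, want_covs = FALSE)
  up_full <- dynbmi:::em_mstep(sm$suffstats, yc, update_dynamics = TRUE)
  up_con <- dynbmi:::em_mstep(sm$suffstats, yc, update_dynamics = FALSE,
                              params = list(M = up_full$M, N = up_full$N))
  expect_identical(up_con, up_full)
})

test_that("LDS parameters round-trip through their JSON artifact", {
  cfg <- small_config()
  s <- small_session(cfg)
  fit <- em_fit(s$spikes[1:1500, ], d = 3, opts = list(max_iter = 20),
                electrode_ids = s$electrode_ids)
  path <- withr::local_tempfile(fileext = ".json")
  write_lds(fit, path)
  back <- read_lds(path)
  expect_equal(back$M, fit$M, tolerance = 0)
  expect_equal(diag(back$R), diag(fit$R), tolerance = 0)
  expect_identical(back$electrode_ids, fit$electrode_ids)
})
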