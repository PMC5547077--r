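# Decoder building blocks: steady-state gain, state inference, readout,
# position blending, intention estimation, FIT-KF, OLE, offline decoding.

test_that("steady-state gain limits behave as the filter equations dictate", {
  # no process noise, no initial uncertainty: nothing to correct, K = 0
  p0 <- lds_params(M = matrix(1), N = matrix(1e-300), P = matrix(1),
                   R = matrix(1), pi1 = 0, S1 = matrix(1e-300))
  expect_lt(abs(steady_state_gain(p0, sigma0 = matrix(0))$K), 1e-12)

  withr::local_seed(11)
  d <- 4; E <- 6
  cfg <- synth_config(n_electrodes = E, latent_dim = d, n_drive_dims = 0,
                      rotation_frequencies_hz = c(1, 2), seed = 11)
  tr <- make_ground_truth(cfg)
  params <- lds_params(tr$M, tr$N, tr$P, tr$R, rep(0, d), diag(1, d))
  K <- steady_state_gain(params)$K
  big <- params; big$R <- params$R * 1e6
  K_big <- steady_state_gain(big)$K
  expect_lt(max(abs(K_big)), 1e-3 * max(abs(K)))
})

test_that("steady-state gain equals the long-run fixed point of the gain recursion", {
  withr::local_seed(12)
  d <- 4; E <- 5
  cfg <- synth_config(n_electrodes = E, latent_dim = d, n_drive_dims = 0,
                      rotation_frequencies_hz = 1.5, seed = 12)
  tr <- make_ground_truth(cfg)
  params <- lds_params(tr$M, tr$N, tr$P, tr$R, rep(0, d), diag(1, d))
  K <- steady_state_gain(params)$K
  # oracle: brute-force iteration of the textbook covariance recursion
  M <- tr$M; N <- tr$N; P <- tr$P; R <- tr$R
  Sigma <- diag(1, d)
  for (i in 1:10000) {
    Sp <- M %*% Sigma %*% t(M) + N
    S <- P %*% Sp %*% t(P) + R
    K_or <- t(solve(S, P %*% Sp))
    Sigma <- (diag(d) - K_or %*% P) %*% Sp
  }
  expect_lt(max(abs(K - K_or)), 1e-9)
})

test_that("state inference converges to the fixed point and matches the full filter", {
  withr::local_seed(13)
  d <- 3; E <- 5
  cfg <- synth_config(n_electrodes = E, latent_dim = d, n_drive_dims = 0,
                      rotation_frequencies_hz = 1, seed = 13)
  tr <- make_ground_truth(cfg)
  params <- lds_params(tr$M, tr$N, tr$P, tr$R, rep(0, d), diag(1, d))

  # constant observations from a fixed latent point: inference converges to it
  s_bar <- c(1, -0.5, 2)
  Y_fix <- matrix(rep(drop(tr$P %*% s_bar), each = 600), 600, E)
  small_noise <- params; small_noise$R <- diag(1e-10, E)
  st <- infer_states(small_noise, Y_fix)
  expect_lt(max(abs(st[600, ] - s_bar)), 1e-6)

  # zero gain: pure autonomous rollout M^k pi1
  p2 <- params; p2$pi1 <- c(1, 1, 1)
  dec <- structure(list(kind = "ndf", lds = p2, K = matrix(0, d, E),
                        electrode_ids = sprintf("e%03d", 1:E),
                        bin_width_s = 0.015),
                   class = "bmi_decoder")
  Y0 <- matrix(0, 5, E)
  st0 <- infer_states(dec, Y0)
  expect_equal(st0[3, ], drop(tr$M %*% tr$M %*% tr$M %*% p2$pi1),
               tolerance = 1e-12)

  # agreement with the exact time-varying Kalman filter after burn-in
  sim <- simulate_lds(tr, 2000, seed = 13)
  st_ss <- infer_states(params, sim$y)
  st_kf <- dynbmi:::cpp_kf_filter_means(sim$y, tr$M, tr$N, tr$P,
                                        diag(tr$R), rep(0, d), diag(1, d))
  burn <- 334  # ~5 s of 15 ms bins
  expect_lt(max(abs(st_ss[burn:2000, ] - st_kf[burn:2000, ])), 1e-4)
})

test_that("the readout solves its least-squares problem exactly", {
  withr::local_seed(14)
  S <- matrix(rnorm(400 * 5), 400, 5)
  L_true <- matrix(rnorm(4 * 6), 4, 6)
  X <- cbind(S, 1) %*% t(L_true)
  ro <- fit_readout(S, X)
  expect_lt(max(abs(ro$L_s - L_true)), 1e-9)

  # intercept-only: zero states give the mean kinematics in the bias column
  S0 <- matrix(0, 300, 3)
  expect_error(fit_readout(S0, matrix(rnorm(1200), 300, 4)),
               class = "dynbmi_rank_error")
  ro0 <- fit_readout(S0, matrix(rep(c(1, 2, 3, 4), each = 300), 300, 4),
                     ridge = 1e-8)
  expect_equal(ro0$L_s[, 4], c(1, 2, 3, 4), tolerance = 1e-4)

  # random instance vs an independent pseudo-inverse oracle
  X2 <- X + matrix(rnorm(1600, sd = 0.3), 400, 4)
  ro2 <- fit_readout(S, X2)
  Sb <- cbind(S, 1)
  L_or <- t(MASS::ginv(Sb) %*% X2)
  expect_lt(max(abs(ro2$L_s - L_or)), 1e-9)
})

test_that("position blending follows the stated convex combination", {
  expect_equal(blend_position(c(1, 1), c(5, 5), c(2, 2), alpha = 0, dt = 0.015),
               c(1, 1))
  expect_equal(blend_position(c(1, 1), c(5, 5), c(2, 2), alpha = 1, dt = 0.015),
               c(5, 5) + c(2, 2) * 0.015)
  expect_equal(blend_position(c(1, 1), c(0, 0), c(10, 0), alpha = 0.975,
                              dt = 0.015),
               c(0.17125, 0.025), tolerance = 1e-12)
})

test_that("intention estimation rotates velocities to the target and zeroes them in the window", {
  trials <- tibble::tibble(trial_id = 1L, target_x_cm = 10, target_y_cm = 0,
                           start_bin = 0L, end_bin = 4L, success = TRUE)
  kin <- rbind(
    c(0, 0, 3, 4),     # moving, must rotate toward bearing 0 -> (5, 0)
    c(0, 0, 5, 0),     # already pointing at the target: unchanged
    c(9, 0, 1, 1),     # inside the 4 cm window: zeroed
    c(0, 0, 0, 0))     # zero velocity: left unchanged
  out <- intention_transform(kin, trials, acceptance_window_cm = 4)
  expect_equal(out[1, 3:4], c(5, 0), tolerance = 1e-12)
  expect_equal(out[2, 3:4], c(5, 0))
  expect_equal(out[3, 3:4], c(0, 0))
  expect_equal(out[4, 3:4], c(0, 0))
  expect_equal(out[, 5], rep(1, 4))
  # speed preserved wherever a rotation occurred
  expect_equal(sqrt(sum(out[1, 3:4]^2)), sqrt(sum(kin[1, 3:4]^2)))
})

test_that("FIT-KF system matrices match the closed-form estimates on a tiny example", {
  # 8 hand-written bins (a 5-dim state needs at least 6 for full rank)
  Xt <- rbind(px = c(0, 1, 2, 2.5, 3, 2, 1, 0.5),
              py = c(0, 0.5, 1.5, 2, 1, 0.5, 0.2, 0),
              vx = c(1, 1.5, 0.5, -0.5, -1, -1.5, -0.5, 0),
              vy = c(0.5, 1, 1, -0.3, -0.8, -0.4, -0.1, 0),
              bias = rep(1, 8))
  Y <- rbind(c(2, 3, 1, 0, 2, 4, 1, 0), c(0, 1, 2, 3, 1, 0, 2, 1))
  K_b <- ncol(Xt)
  X1 <- Xt[, -K_b]; X2 <- Xt[, -1]
  A_or <- X2 %*% t(X1) %*% solve(X1 %*% t(X1))
  W_or <- (X2 - A_or %*% X1) %*% t(X2 - A_or %*% X1) / (K_b - 1)
  C_or <- Y %*% t(Xt) %*% solve(Xt %*% t(Xt))
  Q_or <- (Y - C_or %*% Xt) %*% t(Y - C_or %*% Xt) / K_b
  est <- dynbmi:::fitkf_ml_estimates(Xt, Y)
  expect_equal(est$A, A_or, tolerance = 1e-12)
  expect_equal(est$W, W_or, tolerance = 1e-12)
  expect_equal(est$C, C_or, tolerance = 1e-12)
  expect_equal(est$Q, Q_or, tolerance = 1e-12)
})

test_that("the plain kinematic Kalman filter is near-exact when spikes encode kinematics noiselessly", {
  cfg <- small_config()
  s <- small_session(cfg)
  # overwrite spikes with a noiseless linear encoding of the kinematics
  withr::local_seed(15)
  G <- matrix(rnorm(24 * 5, sd = 0.5), 24, 5)
  Yl <- cbind(s$kinematics, 1) %*% t(G)
  s$spikes <- matrix(as.integer(round(Yl * 100)), nrow(Yl), ncol(Yl))
  s$spikes <- s$spikes - min(s$spikes)
  storage.mode(s$spikes) <- "integer"
  sp <- split_train_test(s, 0.8)
  dec <- train_fitkf(s, sp, intention_estimation = FALSE)
  out <- decode_offline(dec, s, sp$test_trial_ids)
  truth <- s$kinematics[out$bin, ]
  r <- (cor(out$vx, truth[, 3]) + cor(out$vy, truth[, 4])) / 2
  expect_gt(r, 0.99)
})

test_that("the FIT-KF bias state stays pinned at one while decoding", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  dec <- train_fitkf(s, sp, intention_estimation = TRUE)
  # replicate the decode loop, tracking the bias component
  bins <- dynbmi:::trial_bins(s$trials[s$trials$trial_id %in% sp$test_trial_ids, ])
  Y <- s$spikes[bins, ]
  x <- c(0, 0, 0, 0, 1)
  worst <- 0
  fk <- dec$fitkf
  for (k in seq_len(200)) {
    xp <- fk$A %*% x
    x <- drop(xp + fk$K %*% (Y[k, ] - fk$C %*% xp))
    worst <- max(worst, abs(x[5] - 1))
    x[5] <- 1
  }
  expect_lt(worst, 1e-6)
})

test_that("the OLE kernel is causal and normalized, and OLE solves its regression exactly", {
  w <- ole_kernel(0.1, 0.015)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  expect_gt(w[1], w[2])          # decaying into the past, nothing in the future

  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  # construct kinematics exactly linear in the smoothed spikes
  withr::local_seed(16)
  Ys <- dynbmi:::smooth_causal(s$spikes, w)
  L_true <- matrix(rnorm(4 * 25, sd = 0.2), 4, 25)
  s$kinematics <- cbind(Ys, 1) %*% t(L_true)
  dec <- train_ole(s, sp)
  expect_lt(max(abs(dec$ole$L_y - L_true)), 1e-9)

  # random instance vs pseudo-inverse oracle
  s2 <- small_session(cfg)
  dec2 <- train_ole(s2, sp)
  idx <- dynbmi:::trial_bins(s2$trials[s2$trials$trial_id %in% sp$train_trial_ids, ])
  Yb <- cbind(dynbmi:::smooth_causal(s2$spikes, w)[idx, ], 1)
  L_or <- t(MASS::ginv(Yb) %*% s2$kinematics[idx, ])
  expect_lt(max(abs(dec2$ole$L_y - L_or)), 1e-8)
})

test_that("offline decoding resets the position to truth at every trial start", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  for (train in list(function() train_ndf(s, sp, d = 4, opts = list(max_iter = 30)),
                     function() train_fitkf(s, sp),
                     function() train_ole(s, sp))) {
    dec <- train()
    out <- decode_offline(dec, s, sp$test_trial_ids)
    tr <- s$trials[s$trials$trial_id %in% sp$test_trial_ids, ]
    first_rows <- match(tr$start_bin + 1L, out$bin)
    err <- sqrt((out$px[first_rows] - s$kinematics[tr$start_bin + 1, 1])^2 +
                  (out$py[first_rows] - s$kinematics[tr$start_bin + 1, 2])^2)
    expect_equal(max(err), 0)
  }
})

test_that("decoder training is deterministic given the session and split", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  d1 <- train_ndf(s, sp, d = 4, opts = list(max_iter = 25))
  d2 <- train_ndf(s, sp, d = 4, opts = list(max_iter = 25))
  expect_identical(d1$lds$M, d2$lds$M)
  expect_identical(d1$readout$L_s, d2$readout$L_s)
})

test_that("MNDF on an unchanged electrode set with a freshly fit LDS decodes like the NDF", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  ndf <- train_ndf(s, sp, d = 4, opts = list(max_iter = 30))
  mndf <- train_hysteresis(s, sp, remembered = ndf$lds, mode = "mndf")
  o1 <- decode_offline(ndf, s, sp$test_trial_ids)
  o2 <- decode_offline(mndf, s, sp$test_trial_ids)
  expect_lt(max(abs(as.matrix(o1[, c("px", "py", "vx", "vy")]) -
                      as.matrix(o2[, c("px", "py", "vx", "vy")]))), 1e-9)
})

test_that("HNDF training returns the remembered dynamics bit-for-bit", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  cfg2 <- cfg; cfg2$seed <- 99L
  hist <- generate_session(make_ground_truth(cfg), cfg2)
  remembered <- em_fit(hist$spikes, d = 4, opts = list(max_iter = 30))
  hndf <- train_hysteresis(s, sp, remembered, mode = "hndf",
                           opts = list(max_iter = 30))
  expect_identical(hndf$lds$M, remembered$M)
  expect_identical(hndf$lds$N, remembered$N)
})

test_that("MNDF refuses electrodes whose identity is not in the remembered set", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  ndf <- train_ndf(s, sp, d = 4, opts = list(max_iter = 20))
  remembered <- ndf$lds
  remembered$electrode_ids <- NULL
  expect_error(train_hysteresis(s, sp, remembered, mode = "mndf"),
               "identities")
})

test_that("a readout degenerate in one axis loses that degree of freedom while a healthy one spans both", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  healthy <- train_ndf(s, sp, d = 4, opts = list(max_iter = 30))
  crippled <- healthy
  crippled$readout$L_s[3, ] <- 0        # cannot generate x-velocity
  o_h <- decode_offline(healthy, s, sp$test_trial_ids)
  o_c <- decode_offline(crippled, s, sp$test_trial_ids)
  ratio_h <- var(o_h$vx) / var(o_h$vy)
  ratio_c <- var(o_c$vx) / var(o_c$vy)
  expect_equal(var(o_c$vx), 0)
  expect_gt(ratio_h, 100 * ratio_c)
})

test_that("decoding with mismatched electrodes is rejected", {
  cfg <- small_config()
  s <- small_session(cfg)
  sp <- split_train_test(s, 0.8)
  dec <- train_ole(s, sp)
  s2 <- drop_electrodes(s, "e001")
  expect_error(decode_offline(dec, s2), "electrode")
})
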