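# Fixtures are generated in code: a tiny deterministic session for I/O and
# metric tests, and small synthetic configurations for model-based tests.

tiny_session <- function(T_bins = 100, E = 4, n_trials = 4, seed = 42) {
  withr::local_seed(seed)
  spikes <- matrix(rpois(T_bins * E, lambda = 0.5), T_bins, E)
  kin <- cbind(cumsum(rnorm(T_bins, sd = 0.1)), cumsum(rnorm(T_bins, sd = 0.1)),
               rnorm(T_bins, sd = 5), rnorm(T_bins, sd = 5))
  len <- T_bins %/% n_trials
  starts <- (seq_len(n_trials) - 1L) * len
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials),
    target_x_cm = rep(c(0, 12, 0, -12), length.out = n_trials),
    target_y_cm = 0,
    start_bin = starts, end_bin = starts + len, success = TRUE)
  bmi_session(spikes, kin, trials)
}

small_config <- function(...) {
  defaults <- list(n_electrodes = 24, n_trials = 60, latent_dim = 6,
                   rotation_frequencies_hz = c(1.5), seed = 7)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

small_session <- function(cfg = small_config()) {
  generate_session(make_ground_truth(cfg), cfg)
}

# max relative eigenvalue discrepancy after optimal pairing (brute-force
# over permutations; fine for small d)
eig_rel_err <- function(M_fit, M_true) {
  lt <- eigen(M_true, only.values = TRUE)$values
  lf <- eigen(M_fit, only.values = TRUE)$values
  d <- length(lt)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(d))) {
    err <- max(Mod(lf[p] - lt) / Mod(lt))
    if (err < best) best <- err
  }
  best
}

# log-likelihood trace monotone within relative slack
ll_monotone <- function(trace, slack = 1e-8) {
  all(diff(trace) > -slack * (abs(trace[-length(trace)]) + 1))
}

# condition-averaged trajectories from known continuous-time linear dynamics
make_traj_psths <- function(A_cont, n_cond = 8, T_bins = 40, d = 6,
                            dt = 0.015, seed = 1) {
  # embed d-dim linear dynamics into a higher-dim "electrode" space
  withr::local_seed(seed)
  E <- 20
  W <- qr.Q(qr(matrix(rnorm(E * d), E, d)))
  ps <- array(0, dim = c(n_cond, T_bins, E))
  # condition-symmetric starts (+x0 / -x0 pairs) keep the grand mean at zero
  x0s <- matrix(rnorm(d * n_cond / 2), ncol = n_cond / 2)
  x0s <- cbind(x0s, -x0s)
  for (ci in seq_len(n_cond)) {
    x <- x0s[, ci]
    X <- matrix(0, T_bins, d)
    for (k in seq_len(T_bins)) {
      x <- x + dt * drop(A_cont %*% x)
      X[k, ] <- x
    }
    ps[ci, , ] <- X %*% t(W)
  }
  ps
}
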