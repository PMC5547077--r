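#' Configuration for the synthetic session generator
#'
#' Describes a ground-truth latent LDS and a center-out-and-back task used
#' to generate sessions with a known answer. Defaults emulate the recording
#' conditions the decoders are designed for: 96 electrodes, ~500 trials,
#' a 20-dimensional latent state with rotational structure in the 0.5-2.5 Hz
#' band, 8 radial targets on a 12 cm circle, 15 ms bins, and a log-normal
#' spread of electrode informativeness so that mutual-information ranking is
#' non-degenerate.
#'
#' @param n_electrodes number of electrodes (default 96).
#' @param n_trials total number of prompted targets, center and radial
#'   prompts alternating (default 500).
#' @param latent_dim latent state dimension d (default 20).
#' @param rotation_frequencies_hz rotational-mode frequencies (Hz); each
#'   occupies a 2-d block of the dynamics matrix.
#' @param rotation_time_constant_s decay time constant of rotational modes.
#' @param decay_time_constants_s time constants used (recycled) for the
#'   purely decaying modes that fill the remaining dimensions.
#' @param n_drive_dims latent dimensions receiving the per-trial
#'   target-aligned drive (0 or 2).
#' @param drive_time_constant_s decay time constant of the drive dimensions.
#' @param target_radius_cm radius of the radial-target circle (default 12).
#' @param n_targets number of radial targets (default 8).
#' @param drive_gain input gain into the drive dimensions per bin.
#' @param rotation_drive_gain input gain coupling target direction into
#'   rotational modes (condition-dependent rotations).
#' @param process_noise_sd per-bin process noise s.d. on non-rotational
#'   dimensions.
#' @param rotation_noise_sd per-bin process noise s.d. on rotational
#'   dimensions (sets their stationary amplitude).
#' @param baseline_range_hz range of per-electrode baseline firing rates.
#' @param gain_meanlog,gain_sdlog log-normal parameters of the per-electrode
#'   signal gain (informativeness profile).
#' @param gains optional explicit per-electrode gains overriding the
#'   log-normal draw (length `n_electrodes`).
#' @param velocity_gain_cm_s cm/s of cursor velocity per unit of drive state.
#' @param kinematic_noise_sd_cm_s measurement noise s.d. added to velocity.
#' @param reach_duration_bins mean trial duration in bins.
#' @param reach_duration_jitter_bins half-width of the uniform jitter on
#'   trial duration.
#' @param bin_width_s bin width in seconds (default 0.015).
#' @param seed integer seed fixing all randomness.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_electrodes = 96,
                         n_trials = 500,
                         latent_dim = 20,
                         rotation_frequencies_hz = c(0.5, 1.0, 1.5, 2.0, 2.5),
                         rotation_time_constant_s = 0.5,
                         decay_time_constants_s = c(0.05, 0.1, 0.2, 0.4),
                         n_drive_dims = 2,
                         drive_time_constant_s = 0.08,
                         target_radius_cm = 12,
                         n_targets = 8,
                         drive_gain = 0.17,
                         rotation_drive_gain = 0.05,
                         process_noise_sd = 0.08,
                         rotation_noise_sd = 0.24,
                         baseline_range_hz = c(7, 60),
                         gain_meanlog = log(0.3),
                         gain_sdlog = 0.8,
                         gains = NULL,
                         velocity_gain_cm_s = 17,
                         kinematic_noise_sd_cm_s = 0.5,
                         reach_duration_bins = 48,
                         reach_duration_jitter_bins = 8,
                         bin_width_s = 0.015,
                         seed = 1L) {
  cfg <- as.list(environment())
  assert_that(n_targets >= 2, "need at least 2 targets")
  assert_that(latent_dim >= n_drive_dims + 2 * length(rotation_frequencies_hz),
              "latent_dim too small for requested drive and rotation blocks")
  assert_that(n_drive_dims %in% c(0L, 2L), "n_drive_dims must be 0 or 2")
  assert_that(all(unlist(cfg[c("n_electrodes", "n_trials", "latent_dim",
                               "target_radius_cm", "bin_width_s")]) > 0),
              "config sizes must be positive")
  structure(cfg, class = "synth_config")
}

#' Serialize / restore a generator configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored [synth_config()] (read).
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$gains <- if (length(x$gains)) unlist(x$gains) else NULL
  do.call(synth_config, x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the ground-truth LDS from a configuration
#'
#' The dynamics matrix is block-diagonal: optional drive dimensions with a
#' fast real decay, one decaying 2x2 rotation block per requested frequency,
#' and real decay modes filling the remainder. Each rotation block is
#' constructed so that the continuous-time eigenvalues of `(M - I)/dt` have
#' imaginary parts exactly `2 pi f`, i.e. the designed frequencies are
#' recovered in closed form by [eigenmodes()].
#'
#' @param config a [synth_config()].
#' @return A list of class `ground_truth_lds` with elements `M`, `N`
#'   (diagonal process covariance), `P` (observation matrix), `R` (diagonal
#'   observation covariance), `L` (4 x d latent-to-kinematics readout,
#'   velocity rows populated), `baseline` (per-electrode mean counts/bin),
#'   `B` (d x 2 target-direction coupling), `d`, and block bookkeeping.
#' @export
make_ground_truth <- function(config) {
  cfg <- config
  dt <- cfg$bin_width_s
  d <- cfg$latent_dim
  freqs <- cfg$rotation_frequencies_hz
  nyq <- 1 / (2 * dt)
  assert_that(all(freqs > 0 & freqs < nyq),
              sprintf("rotation frequencies must lie in (0, %.2f) Hz", nyq))

  with_seed(cfg$seed, {
    M <- matrix(0, d, d)
    Nd <- numeric(d)
    kind <- character(d)
    i <- 1L
    if (cfg$n_drive_dims == 2) {
      a <- exp(-dt / cfg$drive_time_constant_s)
      M[i, i] <- a; M[i + 1, i + 1] <- a
      Nd[i:(i + 1)] <- cfg$process_noise_sd^2
      kind[i:(i + 1)] <- "drive"
      i <- i + 2L
    }
    for (f in freqs) {
      rho <- exp(-dt / cfg$rotation_time_constant_s)
      x <- 2 * pi * f * dt / rho
      assert_that(x < 1, sprintf("frequency %.2f Hz too fast for the %.0f ms bin", f, 1000 * dt))
      theta <- asin(x)   # Im((rho e^{i theta} - 1)/dt) = 2 pi f exactly
      blk <- rho * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      M[i:(i + 1), i:(i + 1)] <- blk
      Nd[i:(i + 1)] <- cfg$rotation_noise_sd^2
      kind[i:(i + 1)] <- "rotation"
      i <- i + 2L
    }
    j <- 1L
    while (i <= d) {
      tau <- cfg$decay_time_constants_s[(j - 1L) %% length(cfg$decay_time_constants_s) + 1L]
      M[i, i] <- exp(-dt / tau)
      Nd[i] <- cfg$process_noise_sd^2
      kind[i] <- "decay"
      i <- i + 1L; j <- j + 1L
    }

    E <- cfg$n_electrodes
    gains <- cfg$gains %||% rlnorm(E, cfg$gain_meanlog, cfg$gain_sdlog)
    assert_that(length(gains) == E, "gains must have one entry per electrode")
    W <- matrix(rnorm(E * d), E, d)
    W[, kind == "drive"] <- W[, kind == "drive"] * 1.5  # drive dims weighted up
    W <- W / pmax(sqrt(rowSums(W^2)), 1e-12)
    P <- W * gains

    baseline <- runif(E, cfg$baseline_range_hz[1], cfg$baseline_range_hz[2]) * dt
    Rd <- baseline + 0.01   # Poisson-like shot noise floor

    L <- matrix(0, 4, d)
    if (cfg$n_drive_dims == 2) {
      L[3, which(kind == "drive")[1]] <- cfg$velocity_gain_cm_s
      L[4, which(kind == "drive")[2]] <- cfg$velocity_gain_cm_s
    }

    B <- matrix(0, d, 2)
    if (cfg$n_drive_dims == 2) {
      B[which(kind == "drive"), ] <- diag(2) * cfg$drive_gain
      rot <- which(kind == "rotation")
      if (length(rot)) B[rot, ] <- matrix(rnorm(length(rot) * 2), ncol = 2) *
          cfg$rotation_drive_gain
    }

    structure(list(M = M, N = diag(Nd, d), P = P, R = diag(Rd, E), L = L,
                   B = B, baseline = baseline, gains = gains, kind = kind,
                   d = d, E = E, bin_width_s = dt),
              class = "ground_truth_lds")
  })
}

#' Simulate the raw LDS (no task drive)
#'
#' Draws `s_k = M s_{k-1} + n_k` and observations `y_k = baseline + P s_k +
#' r_k`. With `counts = TRUE` observations are rounded and clipped at zero
#' to give valid spike counts; otherwise the exact linear-Gaussian
#' observations are returned.
#'
#' @param truth a [make_ground_truth()] object.
#' @param n_bins number of bins to simulate.
#' @param counts round-and-clip observations to integer counts?
#' @param seed integer seed.
#' @return List with `latents` (T x d) and `y` (T x E).
#' @export
simulate_lds <- function(truth, n_bins, counts = FALSE, seed = 1L) {
  d <- truth$d; E <- truth$E
  nsd <- sqrt(diag(truth$N)); rsd <- sqrt(diag(truth$R))
  with_seed(seed, {
    S <- matrix(0, n_bins, d)
    s <- rnorm(d) * nsd
    for (k in seq_len(n_bins)) {
      s <- drop(truth$M %*% s) + rnorm(d) * nsd
      S[k, ] <- s
    }
    Y <- rep(truth$baseline, each = n_bins) + S %*% t(truth$P) +
      matrix(rnorm(n_bins * E), n_bins, E) * rep(rsd, each = n_bins)
    if (counts) Y <- pmax(round(Y), 0)
    list(latents = S, y = Y)
  })
}

#' Generate a synthetic center-out-and-back session
#'
#' Simulates the latent LDS with a per-trial constant input aligned to the
#' prompted target direction (through the drive dimensions and, weakly, the
#' rotational modes), reads out cursor velocity through the ground-truth
#' readout plus measurement noise, integrates position with a reset to the
#' workspace center at the start of each radial prompt, and emits spike
#' counts by rounding and clipping the linear-Gaussian observations.
#' Trials alternate center and radial prompts; radial targets cycle through
#' all directions in randomized blocks.
#'
#' @param truth a [make_ground_truth()] object.
#' @param config the matching [synth_config()].
#' @return A [bmi_session()].
#' @export
generate_session <- function(truth, config) {
  cfg <- config
  assert_that(cfg$n_trials >= cfg$n_targets,
              "n_trials must be at least n_targets to cover all directions")
  dt <- cfg$bin_width_s
  d <- truth$d; E <- truth$E
  nsd <- sqrt(diag(truth$N)); rsd <- sqrt(diag(truth$R))
  angles <- 2 * pi * (seq_len(cfg$n_targets) - 1) / cfg$n_targets
  radial <- cbind(cfg$target_radius_cm * cos(angles),
                  cfg$target_radius_cm * sin(angles))

  with_seed(cfg$seed + 104729L, {
    # prompted-target sequence: center, radial, center, radial, ...
    n <- cfg$n_trials
    is_radial <- seq_len(n) %% 2 == 0
    n_rad <- sum(is_radial)
    order_idx <- unlist(lapply(seq_len(ceiling(n_rad / cfg$n_targets)),
                               function(i) sample.int(cfg$n_targets)))[seq_len(n_rad)]
    targets <- matrix(0, n, 2)
    targets[is_radial, ] <- radial[order_idx, , drop = FALSE]

    durs <- cfg$reach_duration_bins +
      sample.int(2 * cfg$reach_duration_jitter_bins + 1, n, replace = TRUE) -
      cfg$reach_duration_jitter_bins - 1L
    T_total <- sum(durs)

    S <- matrix(0, T_total, d)
    V <- matrix(0, T_total, 2)
    Pos <- matrix(0, T_total, 2)
    s <- rnorm(d) * nsd
    p <- c(0, 0)
    k <- 0L
    starts <- integer(n); ends <- integer(n)
    for (tr in seq_len(n)) {
      starts[tr] <- k
      if (is_radial[tr]) p <- c(0, 0)  # radial prompts begin at center
      dir <- targets[tr, ] - p
      nrm <- sqrt(sum(dir^2))
      u <- if (nrm > 1e-9) dir / nrm else c(0, 0)
      drive <- drop(truth$B %*% u)
      for (b in seq_len(durs[tr])) {
        k <- k + 1L
        s <- drop(truth$M %*% s) + drive + rnorm(d) * nsd
        S[k, ] <- s
        v <- drop(truth$L[3:4, , drop = FALSE] %*% s) +
          rnorm(2) * cfg$kinematic_noise_sd_cm_s
        p <- p + v * dt
        V[k, ] <- v
        Pos[k, ] <- p
      }
      ends[tr] <- k
    }

    Y <- rep(truth$baseline, each = T_total) + S %*% t(truth$P) +
      matrix(rnorm(T_total * E), T_total, E) * rep(rsd, each = T_total)
    spikes <- pmax(round(Y), 0)
    storage.mode(spikes) <- "integer"

    trials <- tibble::tibble(
      trial_id = seq_len(n), target_x_cm = targets[, 1],
      target_y_cm = targets[, 2], start_bin = starts, end_bin = ends,
      success = TRUE)
    bmi_session(spikes = spikes, kinematics = cbind(Pos, V), trials = trials,
                bin_width_s = dt)
  })
}
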