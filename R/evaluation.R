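#' Lagged velocity correlation
#'
#' Pearson correlation between decoded and true velocity, computed per axis
#' and averaged, at each temporal lag in `lags_s`; the lag maximizing the
#' mean correlation is reported. A positive lag means the decoded (neural)
#' trace leads the kinematics: decoded bin `k` is paired with true bin
#' `k + lag`.
#'
#' @param decoded T x 2 decoded velocities.
#' @param truth T x 2 true velocities.
#' @param lags_s lags to evaluate, in seconds (default 15-90 ms in 15 ms
#'   steps); must be multiples of the bin width.
#' @param dt bin width in seconds.
#' @return One-row tibble: `velocity_correlation` (mean per-axis r at the
#'   best lag), `best_lag_s`, `r_x`, `r_y`. The best lag maximizes the
#'   absolute mean correlation (so a perfectly anti-correlated decode
#'   reports -1, not the weakest negative lag); the signed value is
#'   returned.
#' @export
velocity_correlation <- function(decoded, truth,
                                 lags_s = seq(0.015, 0.090, by = 0.015),
                                 dt = 0.015) {
  decoded <- as_num_matrix(decoded, "decoded")
  truth <- as_num_matrix(truth, "truth")
  assert_that(nrow(decoded) == nrow(truth), "decoded and truth lengths differ")
  lags <- as.integer(round(lags_s / dt))
  assert_that(all(abs(lags * dt - lags_s) < 1e-9), "lags must be multiples of dt")
  T_bins <- nrow(decoded)
  for (ax in 1:2) {
    assert_that(sd(truth[, ax]) > 0 && sd(decoded[, ax]) > 0,
                paste0("zero variance on axis ", c("x", "y")[ax]))
  }
  best <- NULL
  for (i in seq_along(lags)) {
    l <- lags[i]
    a <- decoded[seq_len(T_bins - l), , drop = FALSE]
    b <- truth[seq.int(1 + l, T_bins), , drop = FALSE]
    r_x <- cor(a[, 1], b[, 1]); r_y <- cor(a[, 2], b[, 2])
    r <- (r_x + r_y) / 2
    if (is.null(best) || abs(r) > abs(best$velocity_correlation)) {
      best <- tibble::tibble(velocity_correlation = r,
                             best_lag_s = lags_s[i], r_x = r_x, r_y = r_y)
    }
  }
  best
}

#' Mean position decode error
#'
#' Mean Euclidean norm of the vector from true to decoded position (cm),
#' minimized over the evaluated lags. Decoding is expected to have reset
#' the position to the true hand position at every trial start so error
#' does not accumulate across trials.
#'
#' @param decoded T x 2 decoded positions (cm).
#' @param truth T x 2 true positions (cm).
#' @param trials optional trial table used to sanity-check bin coverage.
#' @param lags_s lags to evaluate, seconds (0 included by default here
#'   since the reset makes position errors well defined at zero lag).
#' @param dt bin width in seconds.
#' @return One-row tibble: `position_error_cm`, `best_lag_s`.
#' @export
position_error <- function(decoded, truth, trials = NULL,
                           lags_s = seq(0.015, 0.090, by = 0.015),
                           dt = 0.015) {
  decoded <- as_num_matrix(decoded, "decoded")
  truth <- as_num_matrix(truth, "truth")
  assert_that(nrow(decoded) == nrow(truth), "decoded and truth lengths differ")
  if (!is.null(trials)) {
    assert_that(max(trials$end_bin) - min(trials$start_bin) <= nrow(decoded),
                "trial table does not match the decoded block")
  }
  lags <- as.integer(round(lags_s / dt))
  T_bins <- nrow(decoded)
  best <- NULL
  for (i in seq_along(lags)) {
    l <- lags[i]
    a <- decoded[seq_len(T_bins - l), , drop = FALSE]
    b <- truth[seq.int(1 + l, T_bins), , drop = FALSE]
    err <- mean(sqrt(rowSums((a - b)^2)))
    if (is.null(best) || err < best$position_error_cm) {
      best <- tibble::tibble(position_error_cm = err, best_lag_s = lags_s[i])
    }
  }
  best
}

#' Score a trained decoder on held-out trials
#'
#' Decodes the given trials and reports the offline metrics: lagged
#' velocity correlation and position error.
#'
#' @param decoder a trained `bmi_decoder`.
#' @param session the [bmi_session()].
#' @param trial_ids trials to score (e.g. the test set of a split).
#' @param lags_s lag grid in seconds.
#' @return One-row tibble with `kind`, `velocity_correlation`,
#'   `best_lag_s`, `r_x`, `r_y`, `position_error_cm`.
#' @export
score_decoder <- function(decoder, session, trial_ids,
                          lags_s = seq(0.015, 0.090, by = 0.015)) {
  dec <- decode_offline(decoder, session, trial_ids)
  bins <- dec$bin
  truth <- session$kinematics[bins, , drop = FALSE]
  vc <- velocity_correlation(cbind(dec$vx, dec$vy), truth[, 3:4],
                             lags_s = lags_s, dt = session$bin_width_s)
  pe <- position_error(cbind(dec$px, dec$py), truth[, 1:2],
                       lags_s = lags_s, dt = session$bin_width_s)
  dplyr::bind_cols(tibble::tibble(kind = decoder$kind), vc,
                   pe[, "position_error_cm"])
}

train_one_decoder <- function(kind, session, split, d, remembered, opts) {
  switch(kind,
         ndf = train_ndf(session, split, d = d, opts = opts),
         hndf = train_hysteresis(session, split, remembered, "hndf", opts = opts),
         mndf = train_hysteresis(session, split, remembered, "mndf"),
         fitkf = train_fitkf(session, split, TRUE),
         fitkf_plain = train_fitkf(session, split, FALSE),
         ole = train_ole(session, split),
         abort(paste0("unknown decoder kind: ", kind)))
}

#' Electrode-loss sweep on one session
#'
#' Simulates progressive electrode loss: electrodes are removed most
#' informative first ([drop_order()]), and for each drop count each
#' requested decoder is trained on the 80% contiguous training block of
#' the restricted session and scored on the held-out 20%. The HNDF/MNDF
#' use the supplied remembered LDS (fit when all electrodes were
#' available). For dynamical decoders the fitted dynamics are also
#' characterized (maximum eigenfrequency, rotational contribution to the
#' decoded output on the held-out block).
#'
#' @param session today's [bmi_session()].
#' @param remembered historical [lds_params()] for the hysteresis decoders
#'   (may be NULL if only non-hysteresis decoders are requested).
#' @param drop_counts increasing vector of numbers of electrodes to drop.
#' @param decoders decoder kinds to evaluate (default NDF and HNDF).
#' @param d latent dimension for freshly fit decoders.
#' @param train_fraction contiguous training fraction (default 0.8).
#' @param opts EM options passed to the fits.
#' @return A tibble (class `loss_sweep`): one row per (drop count,
#'   decoder) with scores and dynamics characterization.
#' @export
drop_sweep <- function(session, remembered = NULL, drop_counts = c(0, 20, 40, 60, 70, 80),
                       decoders = c("ndf", "hndf"), d = 20,
                       train_fraction = 0.8, opts = list()) {
  assert_that(all(diff(drop_counts) > 0), "drop_counts must be strictly increasing")
  E <- ncol(session$spikes)
  assert_that(max(drop_counts) < E, "cannot drop all electrodes")
  ord <- drop_order(session)
  rows <- list()
  for (nd in drop_counts) {
    sess_d <- drop_electrodes(session, ord[seq_len(nd)])
    if (ncol(sess_d$spikes) < d) {
      warn(sprintf("dropping %d electrodes leaves fewer than d = %d; marking NA", nd, d))
      for (kind in decoders) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          n_dropped = nd, n_electrodes = ncol(sess_d$spikes), decoder = kind,
          velocity_correlation = NA_real_, best_lag_s = NA_real_,
          r_x = NA_real_, r_y = NA_real_, position_error_cm = NA_real_,
          max_frequency_hz = NA_real_, rotational_share = NA_real_,
          regularized_rotational_share = NA_real_)
      }
      next
    }
    split <- split_train_test(sess_d, train_fraction)
    test_bins <- trial_bins(sess_d$trials[sess_d$trials$trial_id %in%
                                            split$test_trial_ids, ])
    for (kind in decoders) {
      dec <- train_one_decoder(kind, sess_d, split, d, remembered, opts)
      sc <- score_decoder(dec, sess_d, split$test_trial_ids)
      dyn <- tibble::tibble(max_frequency_hz = NA_real_,
                            rotational_share = NA_real_,
                            regularized_rotational_share = NA_real_)
      if (kind %in% c("ndf", "hndf", "mndf")) {
        em <- eigenmodes(dec$lds$M, dt = sess_d$bin_width_s)
        rep_ <- mode_contributions(dec, sess_d$spikes[test_bins, , drop = FALSE])
        rs <- rotational_share(rep_)
        dyn <- tibble::tibble(max_frequency_hz = max_frequency(em),
                              rotational_share = rs$rotational_share,
                              regularized_rotational_share =
                                rs$regularized_rotational_share)
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(n_dropped = nd, n_electrodes = ncol(sess_d$spikes)),
        sc[, setdiff(names(sc), "kind")],
        tibble::tibble(decoder = kind), dyn)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("loss_sweep", class(out))
  out
}

#' Multi-seed synthetic electrode-loss experiment
#'
#' The full desk-scale analogue of the electrode-loss study: for each seed
#' a fresh ground truth and two sessions are generated (a historical
#' session used only to learn the remembered dynamics, and today's
#' session), then [drop_sweep()] evaluates the decoders across drop
#' counts.
#'
#' @param config a [synth_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param drop_counts numbers of electrodes to drop.
#' @param seeds integer vector of experiment seeds (default 1:10).
#' @param decoders decoder kinds (default NDF and HNDF).
#' @param d latent dimension for the fits (default `config$latent_dim`).
#' @param opts EM options (e.g. `list(steady_state = TRUE, max_iter = 100)`
#'   for long sweeps).
#' @return A `loss_sweep` tibble with a `seed` column.
#' @export
run_loss_experiment <- function(config, drop_counts = c(0, 20, 40, 60, 70, 80),
                                seeds = 1:10, decoders = c("ndf", "hndf"),
                                d = NULL, opts = list()) {
  d <- d %||% config$latent_dim
  res <- purrr::map_dfr(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    truth <- make_ground_truth(cfg)
    today <- generate_session(truth, cfg)
    cfg_hist <- cfg; cfg_hist$seed <- cfg$seed + 7919L
    hist <- generate_session(truth, cfg_hist)
    remembered <- em_fit(hist$spikes, d = d, opts = opts,
                         electrode_ids = hist$electrode_ids)
    sw <- drop_sweep(today, remembered, drop_counts, decoders, d = d,
                     opts = opts)
    sw$seed <- s
    sw
  })
  class(res) <- c("loss_sweep", class(res))
  res
}

#' Paired decoder comparison across seeds
#'
#' Two-sided Wilcoxon signed-rank test of a metric between two decoders,
#' paired within seed, at each drop count (exact for fewer than 25 pairs).
#'
#' @param sweep a multi-seed `loss_sweep`.
#' @param a,b decoder kinds to compare.
#' @param metric column to compare (default `velocity_correlation`).
#' @return Tibble with `n_dropped`, means of both decoders, and `p_value`.
#' @export
compare_decoders <- function(sweep, a = "hndf", b = "ndf",
                             metric = "velocity_correlation") {
  assert_that("seed" %in% names(sweep), "sweep must carry a seed column")
  sweep |>
    dplyr::filter(.data$decoder %in% c(a, b)) |>
    tidyr::pivot_wider(id_cols = c("seed", "n_dropped"),
                       names_from = "decoder",
                       values_from = dplyr::all_of(metric)) |>
    dplyr::group_by(.data$n_dropped) |>
    dplyr::summarise(
      mean_a = mean(.data[[a]]), mean_b = mean(.data[[b]]),
      p_value = tryCatch(
        stats::wilcox.test(.data[[a]], .data[[b]], paired = TRUE,
                           exact = dplyr::n() < 25)$p.value,
        error = function(e) NA_real_),
      .groups = "drop") |>
    dplyr::rename(!!a := "mean_a", !!b := "mean_b")
}

#' Closed-loop performance metrics from a trial log
#'
#' Computes the three standard closed-loop metrics from a log of prompted
#' targets: targets per minute (successful radial acquisitions per minute
#' of block time), success rate (percentage of radial prompts acquired),
#' and mean acquire time of successful radial targets, excluding the hold
#' period.
#'
#' @param trial_log tibble with columns `prompt_s` (prompt time), `end_s`
#'   (acquisition/failure time), `radial` (logical), `success` (logical),
#'   `hold_s` (hold requirement satisfied before `end_s`).
#' @return One-row tibble: `targets_per_min`, `success_rate_pct`,
#'   `mean_acquire_time_s`.
#' @export
closed_loop_metrics <- function(trial_log) {
  need <- c("prompt_s", "end_s", "radial", "success", "hold_s")
  assert_that(all(need %in% names(trial_log)),
              paste0("trial log needs columns: ", paste(need, collapse = ", ")),
              class = "dynbmi_format_error")
  assert_that(all(trial_log$end_s >= trial_log$prompt_s), "malformed trial log",
              class = "dynbmi_format_error")
  dur_min <- (max(trial_log$end_s) - min(trial_log$prompt_s)) / 60
  rad <- trial_log[trial_log$radial, , drop = FALSE]
  ok <- rad[rad$success, , drop = FALSE]
  tibble::tibble(
    targets_per_min = nrow(ok) / dur_min,
    success_rate_pct = 100 * nrow(ok) / max(nrow(rad), 1),
    mean_acquire_time_s = if (nrow(ok)) mean(ok$end_s - ok$prompt_s - ok$hold_s)
      else NA_real_)
}
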