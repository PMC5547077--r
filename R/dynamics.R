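#' Eigenmodes of the continuous-time dynamics
#'
#' Eigen-decomposes `Mtilde = (M - I) / dt`, the first-order approximation
#' of the continuous-time dynamics. A complex-conjugate pair is a
#' rotational mode oscillating at `|Im(lambda)| / (2 pi)` Hz; the real part
#' sets the decay time constant `-1 / Re(lambda)` (infinite for
#' non-decaying modes). A real-arithmetic block basis (columns `Re(v)`,
#' `Im(v)` for each pair) is cached so downstream mode decompositions stay
#' real.
#'
#' @param M d x d discrete-time dynamics matrix (or an [lds_params()]).
#' @param dt bin width in seconds.
#' @return An `eigenmode_set`: `modes` (tibble with `mode_id`, `type`,
#'   `re`, `im`, `frequency_hz`, `time_constant_s`, `dims`), `U_real`
#'   (real block basis), `M_tilde`.
#' @export
eigenmodes <- function(M, dt = 0.015) {
  if (inherits(M, "lds_params")) M <- M$M
  M <- as_num_matrix(M, "M")
  d <- nrow(M)
  Mt <- (M - diag(d)) / dt
  eg <- eigen(Mt)
  lam <- eg$values
  V <- eg$vectors

  used <- rep(FALSE, d)
  rows <- list()
  U <- matrix(0, d, d)
  col <- 1L
  mode_id <- 0L
  for (i in seq_len(d)) {
    if (used[i]) next
    li <- lam[i]
    if (abs(Im(li)) < 1e-10 * max(1, abs(li))) {
      used[i] <- TRUE
      mode_id <- mode_id + 1L
      U[, col] <- Re(V[, i])
      rows[[mode_id]] <- tibble::tibble(
        mode_id = mode_id, type = "real", re = Re(li), im = 0,
        frequency_hz = 0,
        time_constant_s = if (Re(li) < 0) -1 / Re(li) else Inf,
        dims = list(col))
      col <- col + 1L
    } else {
      # find the unused conjugate partner
      j <- which(!used & seq_len(d) != i &
                   abs(lam - Conj(li)) < 1e-8 * max(1, abs(li)))
      assert_that(length(j) >= 1, "unpaired complex eigenvalue")
      j <- j[1]
      used[c(i, j)] <- TRUE
      v <- if (Im(li) > 0) V[, i] else V[, j]
      lp <- if (Im(li) > 0) li else lam[j]
      mode_id <- mode_id + 1L
      U[, col] <- Re(v); U[, col + 1L] <- Im(v)
      rows[[mode_id]] <- tibble::tibble(
        mode_id = mode_id, type = "rotational", re = Re(lp), im = Im(lp),
        frequency_hz = abs(Im(lp)) / (2 * pi),
        time_constant_s = if (Re(lp) < 0) -1 / Re(lp) else Inf,
        dims = list(c(col, col + 1L)))
      col <- col + 2L
    }
  }
  if (rcond(U) < 1e-10) {
    abort("dynamics matrix is defective (within 1e-10); jitter M slightly",
          class = "dynbmi_defective_error")
  }
  structure(list(modes = dplyr::bind_rows(rows), U_real = U, M_tilde = Mt,
                 dt = dt),
            class = "eigenmode_set")
}

#' @export
print.eigenmode_set <- function(x, ...) {
  cat(sprintf("<eigenmode_set> %d modes (%d rotational)\n",
              nrow(x$modes), sum(x$modes$type == "rotational")))
  invisible(x)
}

#' @method tidy eigenmode_set
#' @export
tidy.eigenmode_set <- function(x, ...) x$modes[, setdiff(names(x$modes), "dims")]

#' Maximum rotational frequency with the time-constant screen
#'
#' The largest eigenmode frequency among modes whose decay time constant is
#' at least `min_time_constant_s` (default 20 ms); faster-decaying modes
#' die out before completing an oscillation and are excluded. Returns 0 if
#' no mode qualifies.
#'
#' @param modes an [eigenmodes()] result.
#' @param min_time_constant_s screening threshold in seconds.
#' @return Frequency in Hz.
#' @export
max_frequency <- function(modes, min_time_constant_s = 0.020) {
  m <- modes$modes
  ok <- m$time_constant_s >= min_time_constant_s
  if (!any(ok)) return(0)
  max(m$frequency_hz[ok])
}

gauss_smooth_cols <- function(X, sigma_s, dt) {
  if (sigma_s <= 0) return(X)
  h <- ceiling(4 * sigma_s / dt)
  w <- exp(-((-h:h) * dt)^2 / (2 * sigma_s^2))
  w <- w / sum(w)
  apply(X, 2, function(col) {
    n <- length(col)
    padded <- c(rep(col[1], h), col, rep(col[n], h))
    as.numeric(stats::filter(padded, w, sides = 2))[(h + 1):(h + n)]
  })
}

#' Condition-averaged responses (PSTHs) for the center-out-and-back task
#'
#' Averages spike counts across trials of the same condition, aligned to
#' trial start. Radial prompts give the 8 "out" conditions; center prompts
#' are labelled by the preceding radial target, giving the 8 "back"
#' conditions (16 in total for the standard task).
#'
#' @param session a [bmi_session()].
#' @param n_bins bins per condition (default: shortest included trial).
#' @return A 3-d array `condition x time x electrode` with condition names.
#' @export
condition_psths <- function(session, n_bins = NULL) {
  tr <- session$trials
  is_radial <- sqrt(tr$target_x_cm^2 + tr$target_y_cm^2) > 1e-9
  cond <- character(nrow(tr))
  ang <- round(atan2(tr$target_y_cm, tr$target_x_cm) * 180 / pi) %% 360
  cond[is_radial] <- paste0("out_", ang[is_radial])
  prev_rad <- c(NA, utils::head(ifelse(is_radial, ang, NA), -1))
  cond[!is_radial] <- ifelse(is.na(prev_rad[!is_radial]), NA,
                             paste0("back_", prev_rad[!is_radial]))
  keep <- !is.na(cond)
  tr <- tr[keep, , drop = FALSE]; cond <- cond[keep]
  durs <- tr$end_bin - tr$start_bin
  n_bins <- n_bins %||% min(durs)
  conds <- sort(unique(cond))
  E <- ncol(session$spikes)
  out <- array(0, dim = c(length(conds), n_bins, E),
               dimnames = list(conds, NULL, session$electrode_ids))
  for (ci in seq_along(conds)) {
    rows_tr <- which(cond == conds[ci] & durs >= n_bins)
    assert_that(length(rows_tr) > 0,
                paste0("no trial long enough for condition ", conds[ci]))
    acc <- matrix(0, n_bins, E)
    for (i in rows_tr) {
      rows <- seq.int(tr$start_bin[i] + 1L, tr$start_bin[i] + n_bins)
      acc <- acc + session$spikes[rows, , drop = FALSE]
    }
    out[ci, , ] <- acc / length(rows_tr)
  }
  out
}

fit_skew_ls <- function(X, D) {
  # min_W ||D - X W'||_F^2 with W skew-symmetric, by explicit normal
  # equations over the d(d-1)/2 free parameters
  d <- ncol(X)
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  p <- nrow(pairs)
  preds <- vector("list", p)
  for (l in seq_len(p)) {
    i <- pairs[l, 1]; j <- pairs[l, 2]
    B <- matrix(0, d, d); B[i, j] <- 1; B[j, i] <- -1
    preds[[l]] <- X %*% t(B)
  }
  G <- matrix(0, p, p); h <- numeric(p)
  for (l in seq_len(p)) {
    h[l] <- sum(D * preds[[l]])
    for (m in l:p) {
      G[l, m] <- G[m, l] <- sum(preds[[l]] * preds[[m]])
    }
  }
  wts <- solve(G, h)
  W <- matrix(0, d, d)
  for (l in seq_len(p)) {
    W[pairs[l, 1], pairs[l, 2]] <- wts[l]
    W[pairs[l, 2], pairs[l, 1]] <- -wts[l]
  }
  W
}

#' jPCA R-squared ratio: rotational fit quality of population dynamics
#'
#' Condition-averaged activity is smoothed (Gaussian, 25 ms s.d.),
#' restricted to a robust reach epoch (200-500 ms after trial start),
#' projected onto the top 6 principal components, and the state derivative
#' (first differences / dt) is regressed on the state twice: once with an
#' unconstrained dynamics matrix `M_best` and once constrained to
#' skew-symmetry `M_skew` (purely rotational, imaginary eigenvalues).
#' The returned ratio `R2_skew / R2_best` is 1 when the population
#' dynamics are purely rotational.
#'
#' @param psths `condition x time x electrode` array ([condition_psths()]).
#' @param dt bin width in seconds.
#' @param smooth_sigma_s PSTH smoothing kernel s.d. (default 0.025).
#' @param epoch_s analysis epoch relative to trial start (default
#'   `c(0.2, 0.5)`); an error is raised if trials are too short.
#' @param n_pcs number of principal components (default 6, i.e. 3 planes).
#' @return List of class `jpca_fit`: `ratio`, `r2_skew`, `r2_best`,
#'   `M_skew`, `M_best`, `plane_frequencies_hz` (from `M_skew`),
#'   `max_frequency_hz`.
#' @export
jpca_r2_ratio <- function(psths, dt = 0.015, smooth_sigma_s = 0.025,
                          epoch_s = c(0.2, 0.5), n_pcs = 6) {
  dims <- dim(psths)
  assert_that(length(dims) == 3 && dims[1] >= 2,
              "psths must be a condition x time x electrode array with >= 2 conditions")
  nC <- dims[1]; T_bins <- dims[2]; E <- dims[3]
  k0 <- ceiling(epoch_s[1] / dt + 0.5)       # bin centers in the epoch
  k1 <- floor(epoch_s[2] / dt + 0.5)
  assert_that(k1 <= T_bins && k1 - k0 + 1 >= 3,
              sprintf("trials too short for the %g-%g s epoch", epoch_s[1], epoch_s[2]))

  sm <- array(0, dim = dims)
  for (ci in seq_len(nC)) {
    sm[ci, , ] <- gauss_smooth_cols(psths[ci, , , drop = TRUE], smooth_sigma_s, dt)
  }
  epoch <- k0:k1
  stacked <- do.call(rbind, lapply(seq_len(nC), function(ci) sm[ci, epoch, ]))
  mu <- colMeans(stacked)
  stacked <- sweep(stacked, 2, mu)
  sv <- svd(stacked, nu = 0, nv = n_pcs)
  assert_that(sum(sv$d > 1e-10 * sv$d[1]) >= n_pcs,
              sprintf("fewer than %d effective dimensions in the epoch data", n_pcs))
  Vp <- sv$v

  Xs <- list(); Ds <- list()
  Te <- length(epoch)
  for (ci in seq_len(nC)) {
    proj <- sweep(sm[ci, epoch, , drop = TRUE], 2, mu) %*% Vp
    Xs[[ci]] <- proj[-Te, , drop = FALSE]
    Ds[[ci]] <- diff(proj) / dt
  }
  X <- do.call(rbind, Xs)
  D <- do.call(rbind, Ds)

  M_best <- t(solve(crossprod(X), crossprod(X, D)))
  M_skew <- fit_skew_ls(X, D)
  sse <- function(M) sum((D - X %*% t(M))^2)
  sst <- sum(D^2)
  r2_best <- 1 - sse(M_best) / sst
  r2_skew <- 1 - sse(M_skew) / sst
  ev <- eigen(M_skew, only.values = TRUE)$values
  freqs <- sort(unique(round(abs(Im(ev)) / (2 * pi), 10)), decreasing = TRUE)
  freqs <- freqs[freqs > 0]
  structure(list(ratio = r2_skew / r2_best, r2_skew = r2_skew,
                 r2_best = r2_best, M_skew = M_skew, M_best = M_best,
                 plane_frequencies_hz = freqs,
                 max_frequency_hz = if (length(freqs)) max(freqs) else 0,
                 n_pcs = n_pcs),
            class = "jpca_fit")
}

#' Contribution of each eigenmode to the decoded output
#'
#' Diagonalizes the decoder's dynamics (`M = U Lambda U^-1`, handled in a
#' real block basis), rotates the inferred states into eigen-coordinates,
#' and decodes velocity separately through the columns of the rotated
#' readout belonging to each real mode or complex plane. Each mode's raw
#' contribution `r_v` is the mean decoded speed (cm/s) it produces; its
#' normalized share divides by the summed contribution of all modes plus a
#' 10 cm/s regularizer that guards against small overall speeds after
#' severe electrode loss. The per-mode velocities sum exactly to the total
#' decoded velocity (minus bias).
#'
#' @param decoder a dynamical `bmi_decoder` (NDF/HNDF/MNDF).
#' @param spikes T x E counts to analyse (typically held-out data).
#' @param regularizer_cm_s the share regularizer (default 10).
#' @return A tibble of class `mode_contribution_report`: one row per mode
#'   with `mode_id`, `type`, `frequency_hz`, `time_constant_s`,
#'   `r_v_cm_s`, `share`.
#' @export
mode_contributions <- function(decoder, spikes, regularizer_cm_s = 10) {
  assert_that(inherits(decoder, "bmi_decoder") &&
                decoder$kind %in% c("ndf", "hndf", "mndf"),
              "mode_contributions needs a dynamical decoder (NDF/HNDF/MNDF)")
  em <- eigenmodes(decoder$lds$M, dt = decoder$bin_width_s)
  S <- infer_states(decoder, spikes)
  St <- t(solve(em$U_real, t(S)))                     # states in mode basis
  d <- decoder$lds$d
  L_vel <- decoder$readout$L_s[3:4, seq_len(d), drop = FALSE]
  Lt <- L_vel %*% em$U_real
  m <- em$modes
  r_v <- numeric(nrow(m))
  vel_parts <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    dims <- m$dims[[i]]
    v <- St[, dims, drop = FALSE] %*% t(Lt[, dims, drop = FALSE])
    vel_parts[[i]] <- v
    r_v[i] <- mean(sqrt(rowSums(v^2)))
  }
  share <- r_v / (sum(r_v) + regularizer_cm_s)
  out <- tibble::tibble(mode_id = m$mode_id, type = m$type,
                        frequency_hz = m$frequency_hz,
                        time_constant_s = m$time_constant_s,
                        r_v_cm_s = r_v, share = share)
  class(out) <- c("mode_contribution_report", class(out))
  attr(out, "regularizer_cm_s") <- regularizer_cm_s
  attr(out, "total_velocity") <- Reduce(`+`, vel_parts)
  attr(out, "decoded_velocity") <- S %*% t(L_vel)
  out
}

#' Rotational share of the decoded output
#'
#' The fraction of the decoded-speed contribution carried by rotational
#' modes versus purely decaying modes. A complex pair only counts as
#' rotational if its decay time constant is at least
#' `min_time_constant_s` (20 ms by default, the same screen used for
#' [max_frequency()]): a pair that decays within a bin or two never
#' completes any fraction of an oscillation and behaves like a decay mode.
#' Set `min_time_constant_s = 0` for the raw complex/real split.
#'
#' `rotational_share` is the pre-regularization proportion (rotational
#' `r_v` over total `r_v`); `regularized_rotational_share` is the sum of
#' the regularized shares of rotational modes, the quantity that shrinks
#' when overall decoded speeds collapse after electrode loss.
#'
#' @param report a [mode_contributions()] report.
#' @param min_time_constant_s oscillation-persistence screen in seconds.
#' @return A one-row tibble with both shares.
#' @export
rotational_share <- function(report, min_time_constant_s = 0.02) {
  rot <- report$type == "rotational" &
    report$time_constant_s >= min_time_constant_s
  total <- sum(report$r_v_cm_s)
  tibble::tibble(
    rotational_share = if (total > 0) sum(report$r_v_cm_s[rot]) / total else 0,
    regularized_rotational_share = sum(report$share[rot]))
}
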