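#' Per-electrode spike-count distribution conditioned on the prompted target
#'
#' Builds the empirical distributions used for mutual-information ranking.
#' Counts live on the support `{0, 1, 2, 3, 4, 5+}` (5 or more spikes in a
#' bin are pooled into "5+"). Every bin of a trial, from target onset to
#' trial end, contributes to the conditional distribution of that trial's
#' prompted target; the center prompt counts as its own condition, so `N_x`
#' is the number of distinct prompted targets. `p_X` is empirical over
#' trials and the marginal `p_Y` is the `p_X`-mixture of the conditionals.
#'
#' @param session a [bmi_session()].
#' @param electrode electrode label or index.
#' @param laplace additive (Laplace) smoothing count per support level for
#'   the conditional histograms; 0 (default) uses raw empirical
#'   frequencies. Useful for very short sessions.
#' @return A `spiking_distribution`: `support`, `p_y`, `p_x`,
#'   `p_y_given_x` (N_x x 6 matrix), `targets` (tibble of conditions).
#' @export
estimate_spiking_distribution <- function(session, electrode, laplace = 0) {
  if (is.character(electrode)) {
    e <- match(electrode, session$electrode_ids)
    assert_that(!is.na(e), paste0("unknown electrode: ", electrode))
  } else {
    e <- as.integer(electrode)
    assert_that(e >= 1 && e <= ncol(session$spikes), "electrode index out of range")
  }
  tr <- session$trials
  assert_that(nrow(tr) > 0, "session has no trials")
  key <- paste(signif(tr$target_x_cm, 10), signif(tr$target_y_cm, 10))
  targets <- tibble::tibble(key = unique(key))
  targets$target_x_cm <- tr$target_x_cm[match(targets$key, key)]
  targets$target_y_cm <- tr$target_y_cm[match(targets$key, key)]
  n_x <- nrow(targets)

  counts <- matrix(0, n_x, 6,
                   dimnames = list(NULL, c("0", "1", "2", "3", "4", "5+")))
  y <- pmin(session$spikes[, e], 5L)
  for (i in seq_len(nrow(tr))) {
    ci <- match(key[i], targets$key)
    rows <- seq.int(tr$start_bin[i] + 1L, tr$end_bin[i])
    tab <- tabulate(y[rows] + 1L, nbins = 6)
    counts[ci, ] <- counts[ci, ] + tab
  }
  assert_that(all(rowSums(counts) > 0), "a target condition has zero bins")
  counts <- counts + laplace
  p_ygx <- counts / rowSums(counts)
  p_x <- as.numeric(table(factor(key, levels = targets$key))) / nrow(tr)
  p_y <- drop(p_x %*% p_ygx)
  structure(list(support = colnames(counts), p_y = p_y, p_x = p_x,
                 p_y_given_x = p_ygx, targets = targets,
                 electrode = session$electrode_ids[e]),
            class = "spiking_distribution")
}

entropy_ <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Mutual information between spiking and reach target
#'
#' `I(X, Y) = H(Y) - H(Y | X)` over the pooled count support, with
#' `0 log 0 = 0`. Reported in bits by default.
#'
#' @param dist a [estimate_spiking_distribution()] result.
#' @param base logarithm base (default 2, i.e. bits).
#' @return Non-negative mutual information.
#' @export
electrode_mutual_information <- function(dist, base = 2) {
  H_y <- entropy_(dist$p_y, base)
  H_ygx <- sum(dist$p_x * apply(dist$p_y_given_x, 1, entropy_, base = base))
  max(H_y - H_ygx, 0)
}

#' Rank all electrodes by mutual information
#'
#' @param session a [bmi_session()].
#' @param base logarithm base (default 2).
#' @return A tibble `electrode_id, mi_bits, rank`, most informative first;
#'   ties broken stably by electrode index.
#' @export
rank_electrodes <- function(session, base = 2) {
  mi <- vapply(seq_len(ncol(session$spikes)), function(e) {
    electrode_mutual_information(estimate_spiking_distribution(session, e),
                                 base = base)
  }, numeric(1))
  ord <- order(-mi, seq_along(mi))
  tibble::tibble(electrode_id = session$electrode_ids[ord],
                 mi_bits = mi[ord], rank = seq_along(ord))
}

#' Electrode drop order (most informative first)
#'
#' The simulated-loss protocol removes the most informative electrodes
#' first, the worst case for a decoder. Restricting a session to "drop the
#' first k" removes exactly the first k labels of this list.
#'
#' @param session a [bmi_session()].
#' @return Character vector of electrode labels in drop order.
#' @export
drop_order <- function(session) {
  assert_that(ncol(session$spikes) >= 2, "need at least 2 electrodes")
  rank_electrodes(session)$electrode_id
}
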