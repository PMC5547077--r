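#' Construct a recording-session object
#'
#' A session holds binned spike counts, cursor kinematics and the trial
#' table for one recording. Spikes are threshold crossings counted in
#' non-overlapping bins (15 ms by default); kinematics are cursor position
#' (cm) and velocity (cm/s) sampled on the same bin grid.
#'
#' @param spikes integer matrix, T bins x E electrodes, non-negative counts.
#' @param kinematics numeric matrix, T x 4, columns `px, py, vx, vy`
#'   (cm, cm, cm/s, cm/s).
#' @param trials data frame with columns `trial_id`, `target_x_cm`,
#'   `target_y_cm`, `start_bin`, `end_bin`, `success`. Bin ranges are
#'   0-based half-open `[start_bin, end_bin)`, disjoint, in temporal order.
#' @param bin_width_s bin width in seconds (default 0.015).
#' @param electrode_ids optional electrode labels (default `e001`, ...).
#'
#' @return An object of class `bmi_session`.
#' @export
bmi_session <- function(spikes, kinematics, trials, bin_width_s = 0.015,
                        electrode_ids = NULL) {
  spikes <- as.matrix(spikes)
  kinematics <- as_num_matrix(kinematics, "kinematics")
  trials <- tibble::as_tibble(trials)
  if (is.null(electrode_ids)) {
    electrode_ids <- sprintf("e%03d", seq_len(ncol(spikes)))
  }
  x <- structure(
    list(spikes = spikes, kinematics = kinematics, trials = trials,
         bin_width_s = bin_width_s, electrode_ids = as.character(electrode_ids)),
    class = "bmi_session")
  validate_session(x)
}

#' Validate a session's invariants
#'
#' Checks the structural invariants: matching bin counts between spikes and
#' kinematics, non-negative integer counts, positive bin width, and a trial
#' table whose half-open bin ranges are ordered, disjoint and within range.
#'
#' @param session a [bmi_session()] object.
#' @return The session, invisibly unchanged, or an error.
#' @export
validate_session <- function(session) {
  s <- session
  assert_that(is.matrix(s$spikes), "spikes must be a matrix",
              class = "dynbmi_format_error")
  assert_that(all(is.finite(s$spikes)) && all(s$spikes >= 0) &&
                all(s$spikes == round(s$spikes)),
              "spike counts must be non-negative integers",
              class = "dynbmi_integrity_error")
  assert_that(nrow(s$spikes) == nrow(s$kinematics),
              sprintf("spikes (T=%d) and kinematics (T=%d) must share rows",
                      nrow(s$spikes), nrow(s$kinematics)),
              class = "dynbmi_integrity_error")
  assert_that(ncol(s$kinematics) == 4, "kinematics must have columns px,py,vx,vy",
              class = "dynbmi_format_error")
  assert_that(is.numeric(s$bin_width_s) && s$bin_width_s > 0,
              "bin_width_s must be > 0", class = "dynbmi_integrity_error")
  assert_that(length(s$electrode_ids) == ncol(s$spikes),
              "electrode_ids must match the number of electrodes",
              class = "dynbmi_integrity_error")
  tr <- s$trials
  need <- c("trial_id", "target_x_cm", "target_y_cm", "start_bin", "end_bin", "success")
  assert_that(all(need %in% names(tr)),
              paste0("trial table must have columns: ", paste(need, collapse = ", ")),
              class = "dynbmi_format_error")
  if (nrow(tr) > 0) {
    T_bins <- nrow(s$spikes)
    assert_that(all(tr$start_bin >= 0) && all(tr$end_bin <= T_bins) &&
                  all(tr$end_bin > tr$start_bin),
                "trial bin ranges must be non-empty and within [0, T)",
                class = "dynbmi_integrity_error")
    if (nrow(tr) > 1) {
      assert_that(all(diff(tr$start_bin) > 0) &&
                    all(tr$start_bin[-1] >= tr$end_bin[-nrow(tr)]),
                  "trial bin ranges must be ordered and disjoint",
                  class = "dynbmi_integrity_error")
    }
  }
  invisible(session)
}

#' @export
print.bmi_session <- function(x, ...) {
  cat(sprintf("<bmi_session> %d bins x %d electrodes (%.0f ms bins), %d trials\n",
              nrow(x$spikes), ncol(x$spikes), 1000 * x$bin_width_s, nrow(x$trials)))
  invisible(x)
}

#' @method tidy bmi_session
#' @export
tidy.bmi_session <- function(x, ...) x$trials

#' @method glance bmi_session
#' @export
glance.bmi_session <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x$spikes), n_electrodes = ncol(x$spikes),
    n_trials = nrow(x$trials), bin_width_s = x$bin_width_s,
    duration_s = nrow(x$spikes) * x$bin_width_s,
    mean_rate_hz = mean(x$spikes) / x$bin_width_s)
}

#' Row indices (1-based) covered by a set of trials
#' @keywords internal
#' @noRd
trial_bins <- function(trials) {
  unlist(lapply(seq_len(nrow(trials)), function(i) {
    seq.int(trials$start_bin[i] + 1L, trials$end_bin[i])
  }), use.names = FALSE)
}

SESSION_FORMAT <- "dynbmi-session"
SESSION_VERSION <- 1L

#' Write a session to its portable container
#'
#' The container is a single versioned JSON file storing the spike matrix,
#' kinematics, trial table, bin width and electrode labels at full numeric
#' precision. Writing is deterministic: the same session always produces
#' byte-identical output. See [read_session()] for the inverse.
#'
#' @param session a [bmi_session()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  payload <- list(
    format = SESSION_FORMAT,
    version = SESSION_VERSION,
    bin_width_s = session$bin_width_s,
    electrode_ids = session$electrode_ids,
    spikes = unname(session$spikes),
    kinematics = unname(session$kinematics),
    trials = as.list(session$trials))
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           matrix = "rowmajor")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a session from its portable container
#'
#' @param path file written by [write_session()].
#' @return A validated [bmi_session()].
#' @export
read_session <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path),
              class = "dynbmi_format_error")
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  assert_that(identical(x$format, SESSION_FORMAT),
              "not a dynbmi session container", class = "dynbmi_format_error")
  assert_that(identical(as.integer(x$version), SESSION_VERSION),
              sprintf("unrecognized session container version '%s'", x$version),
              class = "dynbmi_format_error")
  spikes <- x$spikes
  storage.mode(spikes) <- "integer"
  trials <- tibble::as_tibble(x$trials)
  trials$start_bin <- as.integer(trials$start_bin)
  trials$end_bin <- as.integer(trials$end_bin)
  trials$trial_id <- as.integer(trials$trial_id)
  trials$success <- as.logical(trials$success)
  bmi_session(spikes = spikes, kinematics = x$kinematics, trials = trials,
              bin_width_s = x$bin_width_s, electrode_ids = x$electrode_ids)
}

#' Export / import the trial table as CSV
#'
#' @param session a [bmi_session()].
#' @param path CSV path; columns `trial_id, target_x_cm, target_y_cm,
#'   start_bin, end_bin, success`.
#' @return `path`, invisibly.
#' @export
export_trials_csv <- function(session, path) {
  readr::write_csv(session$trials[, c("trial_id", "target_x_cm", "target_y_cm",
                                      "start_bin", "end_bin", "success")], path)
  invisible(path)
}

#' Contiguous train/test split over trials
#'
#' The first `floor(train_fraction * n)` trials in temporal order form the
#' training block; the remainder are held out. This mirrors the standard
#' offline protocol of training on 80% of contiguous trials and testing on
#' the remaining 20%.
#'
#' @param session a [bmi_session()].
#' @param train_fraction fraction of trials used for training, in (0, 1).
#' @return A list with `train_trial_ids` and `test_trial_ids`.
#' @export
split_train_test <- function(session, train_fraction = 0.8) {
  n <- nrow(session$trials)
  assert_that(n >= 2, "need at least 2 trials to split")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  n_train <- max(1L, floor(train_fraction * n))
  ids <- session$trials$trial_id
  structure(list(train_trial_ids = ids[seq_len(n_train)],
                 test_trial_ids = ids[seq.int(n_train + 1L, n)]),
            class = "train_test_split")
}

#' Restrict a session to a subset of trials (rows re-indexed contiguously)
#' @keywords internal
#' @noRd
subset_session_trials <- function(session, trial_ids) {
  tr <- session$trials[session$trials$trial_id %in% trial_ids, , drop = FALSE]
  assert_that(nrow(tr) > 0, "no matching trials")
  keep <- trial_bins(tr)
  lens <- tr$end_bin - tr$start_bin
  new_end <- cumsum(lens)
  tr$start_bin <- as.integer(new_end - lens)
  tr$end_bin <- as.integer(new_end)
  bmi_session(spikes = session$spikes[keep, , drop = FALSE],
              kinematics = session$kinematics[keep, , drop = FALSE],
              trials = tr, bin_width_s = session$bin_width_s,
              electrode_ids = session$electrode_ids)
}

#' Drop electrodes from a session
#'
#' @param session a [bmi_session()].
#' @param drop electrode labels or integer indices to remove. `drop = NULL`
#'   or an empty vector returns the session unchanged.
#' @return The session restricted to surviving electrodes.
#' @export
drop_electrodes <- function(session, drop = NULL) {
  if (is.null(drop) || length(drop) == 0) return(session)
  if (is.character(drop)) {
    idx <- match(drop, session$electrode_ids)
    assert_that(!anyNA(idx), "unknown electrode id in drop list")
  } else {
    idx <- as.integer(drop)
  }
  keep <- setdiff(seq_along(session$electrode_ids), idx)
  assert_that(length(keep) >= 1, "cannot drop every electrode")
  bmi_session(spikes = session$spikes[, keep, drop = FALSE],
              kinematics = session$kinematics, trials = session$trials,
              bin_width_s = session$bin_width_s,
              electrode_ids = session$electrode_ids[keep])
}
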