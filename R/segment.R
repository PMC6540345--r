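#' Binarize a self-assessment rating into a low/high label
#'
#' Ratings below the threshold map to low (0); ratings at or above it map
#' to high (1). The threshold defaults to the midpoint 5 of the 1-9 scale.
#'
#' @param rating Numeric vector of ratings, each in \[1, 9\].
#' @param threshold Cut point; a rating equal to the threshold is high.
#' @return Integer vector of 0 (low) / 1 (high).
#' @export
#' @examples
#' binarize_rating(c(1, 4.99, 5, 9))
binarize_rating <- function(rating, threshold = 5) {
  if (any(!is.finite(rating) | rating < 1 | rating > 9))
    stop("ratings must lie in [1, 9]", call. = FALSE)
  as.integer(rating >= threshold)
}

#' Cut one trial into non-overlapping fixed-length windows
#'
#' The pre-stimulus baseline is discarded (not subtracted), then the
#' remaining signal is cut into contiguous windows of `window_seconds`;
#' any remainder shorter than one window is dropped.
#'
#' @param trial_signal Numeric `[n_channels x n_samples]` matrix.
#' @param fs Sampling rate in Hz.
#' @param baseline_seconds Leading baseline to discard.
#' @param window_seconds Window length.
#' @param trial_id Identifier used in error messages.
#' @return List of `[n_channels x window_samples]` matrices, one per window.
#' @export
#' @examples
#' segs <- segment_trial(matrix(rnorm(2 * 63 * 128), 2), fs = 128)
#' length(segs)  # 20
segment_trial <- function(trial_signal, fs, baseline_seconds = 3,
                          window_seconds = 3, trial_id = NA) {
  stopifnot(is.matrix(trial_signal), fs > 0, window_seconds > 0)
  n <- ncol(trial_signal)
  n_base <- round(baseline_seconds * fs)
  n_win <- round(window_seconds * fs)
  n_seg <- (n - n_base) %/% n_win
  if (n_seg < 1L)
    stop(sprintf("trial %s too short: %d samples < baseline (%d) + one window (%d)",
                 trial_id, n, n_base, n_win), call. = FALSE)
  lapply(seq_len(n_seg), function(i)
    trial_signal[, (n_base + (i - 1L) * n_win + 1L):(n_base + i * n_win),
                 drop = FALSE])
}

#' Segment a recording and attach binarized labels
#'
#' Applies [segment_trial()] to every trial and binarizes the trial's
#' ratings with [binarize_rating()]; every window inherits its parent
#' trial's labels.
#'
#' @param rec An [eeg_recording()].
#' @param baseline_seconds,window_seconds Passed to [segment_trial()].
#' @param threshold Passed to [binarize_rating()].
#' @return A `segment_set`: list with
#'   `signal` (`[n_segments, n_channels, window_samples]` array), `fs`,
#'   `channel_names`, and `meta` (data frame with `subject_id`, `trial_id`,
#'   `segment_index` (0-based), the four raw ratings and the binary
#'   `valence_label`, `arousal_label`, `dominance_label`).
#' @export
segment_recording <- function(rec, baseline_seconds = 3, window_seconds = 3,
                              threshold = 5) {
  rec <- validate_recording(rec)
  d <- dim(rec$signal)
  n_win <- round(window_seconds * rec$fs)
  if (d[1] == 0L) {
    return(structure(list(
      signal = array(0, c(0L, d[2], n_win)), fs = rec$fs,
      channel_names = rec$channel_names,
      meta = empty_segment_meta()), class = "segment_set"))
  }
  n_base <- round(baseline_seconds * rec$fs)
  n_seg <- (d[3] - n_base) %/% n_win
  if (n_seg < 1L)
    stop(sprintf("trials too short: %d samples < baseline (%d) + one window (%d)",
                 d[3], n_base, n_win), call. = FALSE)
  # all trials share a length, so the cut is one reshape:
  # [trial, ch, samples] -> [trial, ch, window, segment] -> [seg*trial, ch, window]
  post <- rec$signal[, , n_base + seq_len(n_seg * n_win), drop = FALSE]
  sig <- array(aperm(array(post, c(d[1], d[2], n_win, n_seg)),
                     c(4L, 1L, 2L, 3L)),
               c(n_seg * d[1], d[2], n_win))
  n_per <- rep(n_seg, d[1])
  trial_id <- rep(seq_len(d[1]), n_per)
  meta <- data.frame(
    subject_id = rec$subject_id,
    trial_id = trial_id,
    segment_index = unlist(lapply(n_per, seq_len)) - 1L,
    rec$ratings[trial_id, , drop = FALSE])
  for (dim_ in c("valence", "arousal", "dominance"))
    meta[[paste0(dim_, "_label")]] <- binarize_rating(meta[[dim_]], threshold)
  structure(list(signal = sig, fs = rec$fs, channel_names = rec$channel_names,
                 meta = meta),
            class = "segment_set")
}

empty_segment_meta <- function() {
  df <- data.frame(subject_id = character(), trial_id = integer(),
                   segment_index = integer(), valence = numeric(),
                   arousal = numeric(), dominance = numeric(),
                   liking = numeric())
  for (dim_ in c("valence", "arousal", "dominance"))
    df[[paste0(dim_, "_label")]] <- integer()
  df
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<segment_set> %d segments x %d channels x %d samples @ %g Hz (%d trials)\n",
              d[1], d[2], d[3], x$fs, length(unique(x$meta$trial_id))))
  invisible(x)
}
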