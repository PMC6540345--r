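#' The 32 EEG channel names in the standard affective-computing order
#'
#' Ordered channel labels (international 10-20 system) of the 32 EEG
#' electrodes used throughout the package, in the order the DEAP-style
#' per-subject files store them. Peripheral (non-EEG) channels are not part
#' of this list.
#'
#' @return Character vector of 32 unique 10-20 labels.
#' @export
#' @examples
#' deap_channels()
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Construct a multi-channel EEG recording object
#'
#' Bundles one subject's trial-indexed EEG block with its sampling rate,
#' channel labels and per-trial self-assessment ratings, and validates the
#' invariants every downstream stage relies on.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param signal Numeric array `[n_trials, n_channels, n_samples]`,
#'   microvolt-scaled. All values must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of unique 10-20 labels, one per
#'   channel, in storage order.
#' @param ratings Numeric matrix `[n_trials, 4]` of self-assessment ratings
#'   on the continuous 1-9 scale, columns ordered
#'   (valence, arousal, dominance, liking).
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording("s01", array(0, c(2, 3, 8)), fs = 4,
#'                      channel_names = c("Fz", "Cz", "Pz"),
#'                      ratings = matrix(5, 2, 4))
#' rec
eeg_recording <- function(subject_id, signal, fs, channel_names, ratings) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         signal = signal, fs = fs,
         channel_names = as.character(channel_names),
         ratings = ratings),
    class = "eeg_recording")
  validate_recording(rec)
}

rating_dims <- function() c("valence", "arousal", "dominance", "liking")

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  if (!is.array(rec$signal) || length(dim(rec$signal)) != 3L)
    stop("signal must be a 3-d array [trials, channels, samples]", call. = FALSE)
  d <- dim(rec$signal)
  if (d[2] != length(rec$channel_names))
    stop(sprintf("signal has %d channels but %d channel names given",
                 d[2], length(rec$channel_names)), call. = FALSE)
  if (anyDuplicated(rec$channel_names))
    stop("channel names must be unique", call. = FALSE)
  if (length(rec$signal) && !all(is.finite(rec$signal)))
    stop("signal contains non-finite values", call. = FALSE)
  if (!is.matrix(rec$ratings) || ncol(rec$ratings) != 4L)
    stop("ratings must be an [n_trials x 4] matrix (valence, arousal, dominance, liking)",
         call. = FALSE)
  if (nrow(rec$ratings) != d[1])
    stop(sprintf("ratings has %d rows but signal has %d trials",
                 nrow(rec$ratings), d[1]), call. = FALSE)
  if (nrow(rec$ratings)) {
    bad <- which(apply(rec$ratings < 1 | rec$ratings > 9 | !is.finite(rec$ratings),
                       1L, any))
    if (length(bad))
      stop(sprintf("ratings outside [1, 9] in trial(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  colnames(rec$ratings) <- rating_dims()
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<eeg_recording> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Write a recording to its canonical on-disk container
#'
#' One hierarchical binary file per subject, holding the signal tensor,
#' channel names, sampling rate and ratings matrix. The file round-trips
#' bit-exactly through [read_recording()].
#'
#' @param rec A validated [eeg_recording()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  saveRDS(unclass(rec), path)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path Path to a per-subject file.
#' @param dialect `"portable"` for the package's canonical container;
#'   `"deap"` for a serialized object in the DEAP per-subject layout with
#'   elements `data` (40 recorded channels, of which the first 32 are EEG
#'   and are kept; the peripheral channels are discarded) and `labels`
#'   (the `[n_trials x 4]` ratings matrix).
#' @param subject_id Subject identifier to attach when the `deap` dialect
#'   (which stores none) is read; defaults to the file name without
#'   extension.
#' @return A validated [eeg_recording()], channel and trial order preserved
#'   exactly as stored.
#' @export
read_recording <- function(path, dialect = c("portable", "deap"),
                           subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (dialect == "portable") {
    rec <- structure(obj, class = "eeg_recording")
  } else {
    if (is.null(obj$data) || is.null(obj$labels))
      stop("deap dialect requires elements 'data' and 'labels'", call. = FALSE)
    sig <- obj$data
    if (length(dim(sig)) != 3L || dim(sig)[2] < 32L)
      stop("deap 'data' must be [trials x >=32 channels x samples]", call. = FALSE)
    if (is.null(subject_id))
      subject_id <- sub("\\.[^.]*$", "", basename(path))
    rec <- structure(
      list(subject_id = subject_id,
           signal = sig[, seq_len(32L), , drop = FALSE],
           fs = if (!is.null(obj$fs)) obj$fs else 128,
           channel_names = deap_channels(),
           ratings = as.matrix(obj$labels)),
      class = "eeg_recording")
  }
  validate_recording(rec)
}

#' Export a recording's ratings as a sidecar CSV
#'
#' Plain-text companion to the binary container, for quick inspection:
#' columns `trial_id, valence, arousal, dominance, liking`.
#'
#' @inheritParams write_recording
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(rec, path) {
  validate_recording(rec)
  df <- data.frame(trial_id = seq_len(nrow(rec$ratings)), rec$ratings)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
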