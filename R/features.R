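# Band mean-PSD features. The PSD estimator is Welch's method built on
# stats::mvfft (1-s Hann windows, 50% overlap by default); band averages
# use half-open [low, high) bins so shared edges are counted once.

#' Define the frequency-band scheme
#'
#' @param ... Named numeric length-2 vectors `c(low, high)` in Hz, ordered
#'   by low edge. Defaults: theta 4-8, alpha 8-15, beta 15-32, gamma
#'   32-45. Bands may share edges but must not overlap; a shared edge
#'   belongs to the upper band.
#' @return A `band_scheme` object with elements `bands` (named list) and
#'   `names`.
#' @export
#' @examples
#' band_scheme()
band_scheme <- function(...) {
  bands <- list(...)
  if (!length(bands))
    bands <- list(theta = c(4, 8), alpha = c(8, 15),
                  beta = c(15, 32), gamma = c(32, 45))
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop("bands must be named", call. = FALSE)
  for (b in bands)
    if (length(b) != 2L || b[1] >= b[2] || b[1] < 0)
      stop("each band must be c(low, high) with 0 <= low < high", call. = FALSE)
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  o <- order(lo)
  if (any(hi[o][-length(bands)] > lo[o][-1] + 1e-12))
    stop("bands must not overlap (shared edges allowed)", call. = FALSE)
  structure(list(bands = bands[o], names = names(bands)[o]),
            class = "band_scheme")
}

# Hann window (periodic convention).
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Welch power spectral density of one or more signals
#'
#' One-sided PSD in power per Hz, averaged over Hann-tapered windows with
#' the given overlap. Columns of a matrix input are treated as independent
#' signals and share the FFT call.
#'
#' @param x Numeric vector or `[n_samples x n_signals]` matrix.
#' @param fs Sampling rate in Hz.
#' @param window_samples Taper length; defaults to one second.
#' @param overlap Fractional window overlap in \[0, 1).
#' @return List with `freq` (Hz) and `psd`
#'   (`[n_freq x n_signals]` matrix, units x^2/Hz).
#' @export
welch_psd <- function(x, fs, window_samples = round(fs), overlap = 0.5) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  nw <- as.integer(window_samples)
  if (nw > n) stop("segment shorter than the PSD window", call. = FALSE)
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq.int(1L, n - nw + 1L, by = step)
  w <- hann(nw)
  scale <- 1 / (fs * sum(w^2))
  nf <- nw %/% 2L + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L), , drop = FALSE] * w
    sp <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + Re(sp * Conj(sp))
  }
  psd <- acc * (scale / length(starts))
  # one-sided: double everything except DC and (for even nw) Nyquist
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nw %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nw, psd = psd * dbl)
}

band_bin_index <- function(freq, scheme) {
  lapply(scheme$bands, function(b) which(freq >= b[1] & freq < b[2]))
}

#' Mean band PSD of one segment
#'
#' Per channel, the one-sided Welch PSD is averaged over the bins whose
#' frequencies fall in `[low, high)` of each band.
#'
#' @param segment Numeric `[n_channels x n_samples]` matrix.
#' @param fs Sampling rate in Hz.
#' @param scheme A [band_scheme()]; all edges must be below `fs / 2`.
#' @param window_seconds,overlap Welch parameters (taper length in
#'   seconds, fractional overlap).
#' @return `[n_channels x n_bands]` matrix of mean PSD (microV^2/Hz), with
#'   dimnames. Flatten with `as.vector(t(.))` for the channel-major,
#'   band-minor feature vector.
#' @export
#' @examples
#' seg <- matrix(rnorm(2 * 384), 2)
#' band_psd(seg, fs = 128)
band_psd <- function(segment, fs, scheme = band_scheme(),
                     window_seconds = 1, overlap = 0.5) {
  stopifnot(is.matrix(segment))
  hi <- max(vapply(scheme$bands, `[`, numeric(1), 2L))
  if (hi > fs / 2)
    stop(sprintf("band edge %g Hz is above Nyquist (%g Hz)", hi, fs / 2),
         call. = FALSE)
  w <- welch_psd(t(segment), fs, round(window_seconds * fs), overlap)
  idx <- band_bin_index(w$freq, scheme)
  out <- vapply(idx, function(i) colMeans(w$psd[i, , drop = FALSE]),
                numeric(nrow(segment)))
  out <- matrix(out, nrow(segment), length(idx),
                dimnames = list(rownames(segment), scheme$names))
  out
}

#' Compute the per-segment feature table of a segment set
#'
#' One row per segment, one column per (channel, band) pair in
#' channel-major, band-minor order (`Fp1.theta, Fp1.alpha, ...`); 32
#' channels x 4 bands gives the 128-feature layout.
#'
#' @param segments A `segment_set` from [segment_recording()].
#' @param scheme A [band_scheme()].
#' @param window_seconds,overlap Welch parameters, as in [band_psd()].
#' @return A `feature_table`: list with `raw` (`[n_segments x
#'   n_channels*n_bands]` matrix), `normalized` (`NULL` until
#'   [normalize_features()]), `meta`, `channel_names`, `scheme`.
#' @export
feature_table <- function(segments, scheme = band_scheme(),
                          window_seconds = 1, overlap = 0.5) {
  stopifnot(inherits(segments, "segment_set"))
  d <- dim(segments$signal)
  n_seg <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  nb <- length(scheme$bands)
  cols <- as.vector(t(outer(segments$channel_names, scheme$names, paste,
                            sep = ".")))
  raw <- matrix(0, n_seg, n_ch * nb, dimnames = list(NULL, cols))
  if (n_seg > 0L) {
    hi <- max(vapply(scheme$bands, `[`, numeric(1), 2L))
    if (hi > segments$fs / 2)
      stop("band edge above Nyquist", call. = FALSE)
    nw <- as.integer(round(window_seconds * segments$fs))
    if (nw > n_samp) stop("segment shorter than the PSD window", call. = FALSE)
    step <- max(1L, as.integer(round(nw * (1 - overlap))))
    starts <- seq.int(1L, n_samp - nw + 1L, by = step)
    w <- hann(nw)
    nf <- nw %/% 2L + 1L
    freq <- (seq_len(nf) - 1L) * segments$fs / nw
    idx <- band_bin_index(freq, scheme)
    dbl <- rep(2, nf); dbl[1L] <- 1; if (nw %% 2L == 0L) dbl[nf] <- 1
    scale <- dbl / (segments$fs * sum(w^2) * length(starts))
    # batch all (segment, channel) pairs; only the DFT bins inside some band
    # are needed, so evaluate them directly as two real matrix products with
    # the Hann taper folded into the basis (numerically identical to the
    # tapered FFT at those bins)
    bins <- sort(unique(unlist(idx)))
    ang <- outer(bins - 1L, seq_len(nw) - 1L) * (2 * pi / nw)
    basis_c <- cos(ang) * rep(w, each = length(bins))
    basis_s <- sin(ang) * rep(w, each = length(bins))
    acc <- matrix(0, length(bins), n_seg * n_ch)
    flat <- matrix(aperm(segments$signal, c(3L, 2L, 1L)), n_samp, n_seg * n_ch)
    for (s0 in starts) {
      xw <- flat[s0:(s0 + nw - 1L), , drop = FALSE]
      acc <- acc + (basis_c %*% xw)^2 + (basis_s %*% xw)^2
    }
    acc <- acc * scale[bins]
    for (b in seq_len(nb)) {
      m <- colMeans(acc[match(idx[[b]], bins), , drop = FALSE]) # ch-major
      raw[, seq.int(b, by = nb, length.out = n_ch)] <-
        t(matrix(m, n_ch, n_seg))
    }
  }
  structure(list(raw = raw, normalized = NULL, meta = segments$meta,
                 channel_names = segments$channel_names, scheme = scheme,
                 extrema = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d segments x %d features (%d channels x %d bands)%s\n",
              nrow(x$raw), ncol(x$raw), length(x$channel_names),
              length(x$scheme$bands),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Concatenate feature tables of several subjects
#'
#' @param tables List of `feature_table` objects sharing channel names and
#'   band scheme.
#' @return One combined `feature_table` (normalization is dropped;
#'   renormalize after binding).
#' @export
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) > 0L)
  first <- tables[[1L]]
  for (tb in tables) {
    stopifnot(inherits(tb, "feature_table"),
              identical(tb$channel_names, first$channel_names),
              identical(tb$scheme$names, first$scheme$names))
  }
  structure(list(raw = do.call(rbind, lapply(tables, `[[`, "raw")),
                 normalized = NULL,
                 meta = do.call(rbind, lapply(tables, `[[`, "meta")),
                 channel_names = first$channel_names, scheme = first$scheme,
                 extrema = NULL),
            class = "feature_table")
}

norm_column <- function(f, fmax, fmin, orientation) {
  rng <- fmax - fmin
  if (rng <= 0) return(rep(0, length(f)))
  if (orientation == "inverted") (fmax - f) / rng else (f - fmin) / rng
}

#' Min-max normalize features per subject
#'
#' For every feature column, within each subject, applies
#' `F' = (Fmax - F) / (Fmax - Fmin)` with that subject's column extrema:
#' the default orientation maps the column maximum to 0 and the minimum to
#' 1 (order-reversing). `orientation = "standard"` restores the
#' conventional `(F - Fmin) / (Fmax - Fmin)`. A degenerate column
#' (`Fmax == Fmin`) maps to 0.
#'
#' Extrema are taken over all of a subject's segments by default. For a
#' leakage-free variant, pass `extrema_rows` with the (training) row
#' indices the extrema may be computed from; rows outside are normalized
#' with those same extrema and clipped to \[0, 1\].
#'
#' @param table A [feature_table()].
#' @param orientation `"inverted"` (default) or `"standard"`.
#' @param extrema_rows Optional integer row indices restricting extrema
#'   computation (fold-safe mode).
#' @return The table with `normalized` and per-subject `extrema` filled in.
#' @export
normalize_features <- function(table, orientation = c("inverted", "standard"),
                               extrema_rows = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(table, "feature_table"))
  norm <- matrix(0, nrow(table$raw), ncol(table$raw),
                 dimnames = dimnames(table$raw))
  extrema <- list()
  for (sid in unique(table$meta$subject_id)) {
    rows <- which(table$meta$subject_id == sid)
    base <- if (is.null(extrema_rows)) rows else intersect(rows, extrema_rows)
    if (!length(base))
      stop("no extrema rows for subject ", sid, call. = FALSE)
    fmax <- apply(table$raw[base, , drop = FALSE], 2L, max)
    fmin <- apply(table$raw[base, , drop = FALSE], 2L, min)
    for (j in seq_len(ncol(norm)))
      norm[rows, j] <- norm_column(table$raw[rows, j], fmax[j], fmin[j],
                                   orientation)
    if (!is.null(extrema_rows)) norm[rows, ] <- pmin(pmax(norm[rows, ], 0), 1)
    extrema[[sid]] <- list(fmax = fmax, fmin = fmin)
  }
  table$normalized <- norm
  table$extrema <- extrema
  table$orientation <- orientation
  table
}

#' Normalize a single subject's rows of a feature table
#'
#' Same transform as [normalize_features()], restricted to one subject.
#'
#' @inheritParams normalize_features
#' @param subject_id Subject whose rows to normalize.
#' @return The table with that subject's rows of `normalized` filled in.
#' @export
normalize_subject <- function(table, subject_id,
                              orientation = c("inverted", "standard")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(table, "feature_table"))
  rows <- which(table$meta$subject_id == subject_id)
  if (!length(rows)) stop("unknown subject: ", subject_id, call. = FALSE)
  if (is.null(table$normalized))
    table$normalized <- matrix(NA_real_, nrow(table$raw), ncol(table$raw),
                               dimnames = dimnames(table$raw))
  fmax <- apply(table$raw[rows, , drop = FALSE], 2L, max)
  fmin <- apply(table$raw[rows, , drop = FALSE], 2L, min)
  for (j in seq_len(ncol(table$raw)))
    table$normalized[rows, j] <-
      norm_column(table$raw[rows, j], fmax[j], fmin[j], orientation)
  if (is.null(table$extrema)) table$extrema <- list()
  table$extrema[[subject_id]] <- list(fmax = fmax, fmin = fmin)
  table$orientation <- orientation
  table
}
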