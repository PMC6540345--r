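# Topographic mapping: 32 electrodes onto a 9x9 scalp grid per band, and
# 2x2 tiling of the four band grids into the 18x18 multiband feature
# matrix (MFM) the classifier consumes.

#' The canonical 9x9 electrode montage
#'
#' Maps each of the 32 channel labels to a (row, col) cell of a 9x9 grid,
#' 0-based, row 0 anterior (nasion side), column 0 left. Rows run
#' anterior to posterior; homologous left/right pairs occupy mirror
#' columns (`col` and `8 - col`) of the same row, with the midline at
#' column 4 (Cz at (4, 4)). Cells without an electrode take the fill
#' value when a submatrix is built.
#'
#' @return Integer matrix `[32 x 2]` with rownames = channel labels and
#'   columns `row`, `col`.
#' @export
#' @examples
#' deap_montage()["Cz", ]
deap_montage <- function() {
  m <- rbind(
    Fp1 = c(0, 3), Fp2 = c(0, 5),
    AF3 = c(1, 3), AF4 = c(1, 5),
    F7 = c(2, 0), F3 = c(2, 2), Fz = c(2, 4), F4 = c(2, 6), F8 = c(2, 8),
    FC5 = c(3, 1), FC1 = c(3, 3), FC2 = c(3, 5), FC6 = c(3, 7),
    T7 = c(4, 0), C3 = c(4, 2), Cz = c(4, 4), C4 = c(4, 6), T8 = c(4, 8),
    CP5 = c(5, 1), CP1 = c(5, 3), CP2 = c(5, 5), CP6 = c(5, 7),
    P7 = c(6, 0), P3 = c(6, 2), Pz = c(6, 4), P4 = c(6, 6), P8 = c(6, 8),
    PO3 = c(7, 3), PO4 = c(7, 5),
    O1 = c(8, 3), Oz = c(8, 4), O2 = c(8, 5))
  colnames(m) <- c("row", "col")
  storage.mode(m) <- "integer"
  m[deap_channels(), ]
}

validate_montage <- function(montage) {
  stopifnot(is.matrix(montage), ncol(montage) == 2L,
            !is.null(rownames(montage)))
  if (any(montage < 0L | montage > 8L))
    stop("montage coordinates must lie in [0, 8]", call. = FALSE)
  if (anyDuplicated(montage[, 1L] * 9L + montage[, 2L]))
    stop("duplicate montage coordinates", call. = FALSE)
  montage
}

#' Place one band's channel features on the 9x9 grid
#'
#' @param features Named numeric vector, one value per montage channel
#'   (names must match the montage; order is taken from the names).
#' @param montage Channel-to-cell map, see [deap_montage()].
#' @param fill Value for the grid cells without an electrode.
#' @return 9x9 numeric matrix.
#' @export
#' @examples
#' v <- setNames(rep(1, 32), deap_channels())
#' sum(build_submatrix(v) != 0)  # 32
build_submatrix <- function(features, montage = deap_montage(), fill = 0) {
  validate_montage(montage)
  if (is.null(names(features)))
    stop("features must be named by channel", call. = FALSE)
  missing <- setdiff(names(features), rownames(montage))
  if (length(missing))
    stop("channel(s) missing from montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- matrix(fill, 9L, 9L)
  co <- montage[names(features), , drop = FALSE]
  g[co[, "row"] + 1L + 9L * co[, "col"]] <- features
  g
}

#' Tile four band submatrices into an 18x18 MFM
#'
#' @param submatrices Named list of 9x9 matrices, one per band.
#' @param layout Character 2x2 matrix assigning a band to each quadrant;
#'   default theta top-left, alpha top-right, beta bottom-left, gamma
#'   bottom-right.
#' @return 18x18 numeric matrix.
#' @export
assemble_mfm <- function(submatrices,
                         layout = matrix(c("theta", "alpha", "beta", "gamma"),
                                         2L, 2L, byrow = TRUE)) {
  stopifnot(is.matrix(layout), all(dim(layout) == 2L))
  missing <- setdiff(as.vector(layout), names(submatrices))
  if (length(missing))
    stop("missing submatrix for band(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (b in as.vector(layout))
    if (!all(dim(submatrices[[b]]) == 9L))
      stop("submatrix for ", b, " is not 9x9", call. = FALSE)
  out <- matrix(0, 18L, 18L)
  for (qr in 1:2) for (qc in 1:2)
    out[(qr - 1L) * 9L + 1:9, (qc - 1L) * 9L + 1:9] <-
      submatrices[[layout[qr, qc]]]
  out
}

# Linear indices (into the flattened 18x18, column-major) of each feature
# column of a channel-major band-minor feature matrix.
mfm_feature_index <- function(channel_names, scheme, montage, layout) {
  idx <- integer(length(channel_names) * length(scheme$names))
  for (ci in seq_along(channel_names)) {
    rc <- montage[channel_names[ci], ]
    for (bi in seq_along(scheme$names)) {
      q <- which(layout == scheme$names[bi], arr.ind = TRUE)
      r <- (q[1L] - 1L) * 9L + rc[1L] + 1L
      cc <- (q[2L] - 1L) * 9L + rc[2L] + 1L
      idx[(ci - 1L) * length(scheme$names) + bi] <- (cc - 1L) * 18L + r
    }
  }
  idx
}

#' Build the MFM dataset from a normalized feature table
#'
#' One 18x18 MFM per segment, labels carried along.
#'
#' @param table A [feature_table()]; normalized values are used (run
#'   [normalize_features()] first), falling back to raw values with a
#'   warning if normalization is absent.
#' @param montage See [deap_montage()].
#' @param layout Quadrant-to-band assignment, see [assemble_mfm()].
#' @param fill Fill for cells without an electrode.
#' @return An `mfm_set`: list with `mfm` (`[n, 18, 18]` array), `meta`
#'   (the table's segment metadata incl. binary labels), `layout`,
#'   `montage`.
#' @export
mfm_dataset <- function(table, montage = deap_montage(),
                        layout = matrix(c("theta", "alpha", "beta", "gamma"),
                                        2L, 2L, byrow = TRUE),
                        fill = 0) {
  stopifnot(inherits(table, "feature_table"))
  validate_montage(montage)
  vals <- table$normalized
  if (is.null(vals)) {
    warning("feature table not normalized; using raw values")
    vals <- table$raw
  }
  n <- nrow(vals)
  idx <- mfm_feature_index(table$channel_names, table$scheme, montage, layout)
  flat <- matrix(fill, n, 18L * 18L)
  flat[, idx] <- vals
  structure(list(mfm = array(flat, c(n, 18L, 18L)), meta = table$meta,
                 layout = layout, montage = montage),
            class = "mfm_set")
}

#' @export
print.mfm_set <- function(x, ...) {
  cat(sprintf("<mfm_set> %d MFMs of %dx%d\n", dim(x$mfm)[1], dim(x$mfm)[2],
              dim(x$mfm)[3]))
  invisible(x)
}

#' Run the full recording-to-MFM pipeline
#'
#' Convenience wrapper: segment each recording, compute band features,
#' normalize per subject, and build the pooled MFM dataset.
#'
#' @param recordings One [eeg_recording()] or a list of them.
#' @param scheme,montage,layout,orientation Passed to the stages.
#' @param baseline_seconds,window_seconds Passed to [segment_recording()].
#' @return An `mfm_set` pooling all subjects' segments.
#' @export
mfm_pipeline <- function(recordings, scheme = band_scheme(),
                         montage = deap_montage(),
                         layout = matrix(c("theta", "alpha", "beta", "gamma"),
                                         2L, 2L, byrow = TRUE),
                         orientation = "inverted",
                         baseline_seconds = 3, window_seconds = 3) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(r)
    feature_table(segment_recording(r, baseline_seconds, window_seconds),
                  scheme))
  tab <- if (length(tabs) == 1L) tabs[[1L]] else bind_feature_tables(tabs)
  tab <- normalize_features(tab, orientation)
  mfm_dataset(tab, montage, layout)
}

#' Generate a synthetic cohort and run it straight to MFMs
#'
#' Memory-lean variant of [mfm_pipeline()] for whole cohorts: each
#' subject is generated, segmented and reduced to its feature table in
#' turn, so only one subject's raw signal is ever held in memory. The
#' pooled table is normalized per subject and mapped to MFMs.
#'
#' @param cfg A [synth_config()].
#' @param n_subjects Number of subjects to generate.
#' @param orientation Normalization orientation, see
#'   [normalize_features()].
#' @param keep_latent Attach the per-segment latent class as a metadata
#'   column `latent_class`.
#' @return An `mfm_set` with one MFM per segment of every subject.
#' @export
mfm_cohort <- function(cfg, n_subjects = 32, orientation = "inverted",
                       keep_latent = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  ids <- sprintf("s%02d", seq_len(n_subjects))
  tabs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    rec <- generate_recording(cfg, ids[i],
                              seed = (cfg$seed + 7919L * i) %% .Machine$integer.max)
    segs <- segment_recording(rec, cfg$baseline_seconds)
    tabs[[i]] <- feature_table(segs)
    if (keep_latent) {
      n_per <- nrow(segs$meta) / cfg$n_trials
      tabs[[i]]$meta$latent_class <-
        rep(attr(rec, "latent_class"), each = n_per)
    }
  }
  tab <- if (n_subjects == 1L) tabs[[1L]] else bind_feature_tables(tabs)
  tab <- normalize_features(tab, orientation)
  mfm_dataset(tab)
}
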