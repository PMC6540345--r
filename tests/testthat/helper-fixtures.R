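# Small fixtures built in code; every test that needs data constructs it
# from a fixed seed.

# A short hand-built recording: n_trials trials, n_ch channels, n_sec seconds.
make_recording <- function(n_trials = 2, n_ch = 3, n_sec = 9, fs = 128,
                           seed = 1, subject_id = "tst") {
  set.seed(seed)
  eeg_recording(
    subject_id,
    array(rnorm(n_trials * n_ch * n_sec * fs), c(n_trials, n_ch, n_sec * fs)),
    fs = fs,
    channel_names = deap_channels()[seq_len(n_ch)],
    ratings = matrix(runif(n_trials * 4, 1, 9), n_trials, 4))
}

# Wrap a raw feature matrix as a feature_table (single band/channel grid
# inferred from the column count) for normalization tests.
fake_table <- function(raw, subjects = rep("s01", nrow(raw))) {
  n_ch <- ncol(raw)
  structure(list(
    raw = `colnames<-`(raw, paste0(deap_channels()[seq_len(n_ch)], ".alpha")),
    normalized = NULL,
    meta = data.frame(subject_id = subjects,
                      trial_id = seq_len(nrow(raw)),
                      segment_index = 0L),
    channel_names = deap_channels()[seq_len(n_ch)],
    scheme = band_scheme(alpha = c(8, 15)),
    extrema = NULL), class = "feature_table")
}

# Strongly separated toy MFMs: class-dependent level in the alpha
# (top-right) quadrant, mild noise elsewhere.
toy_mfms <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  x <- array(runif(n * 18 * 18, 0, 0.2), c(n, 18, 18))
  for (i in seq_len(n))
    x[i, 1:9, 10:18] <- x[i, 1:9, 10:18] + ifelse(y[i] == 1L, 0.8, 0.1)
  list(x = x, y = y)
}

# A small, fast capsule config for training tests.
small_capsnet <- function(seed = 7, ...) {
  capsnet_config(conv_filters = 16, primary_channels = 32,
                 primary_capsule_dim = 32, emotion_capsule_dim = 8,
                 decoder_units = c(64, 128), seed = seed, ...)
}
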