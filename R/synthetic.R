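# Synthetic EEG with controllable class-dependent band-power structure.
# Background is AR(1)-colored noise; class signal rides on narrowband
# (band-passed noise) or pure-tone carriers added to a channel subset.

#' Describe one class-dependent band-limited signal component
#'
#' @param band Name of the target frequency band (must exist in the
#'   [band_scheme()] used at generation time), for `type = "narrowband"`.
#' @param channels Channel labels the carrier is added to.
#' @param amplitude Baseline carrier amplitude in microvolts (RMS for
#'   narrowband carriers, peak for tones).
#' @param low_gain,high_gain Amplitude multipliers applied for trials of
#'   the low / high latent class. Both must be positive.
#' @param type `"narrowband"` (band-pass filtered white noise centered in
#'   the band, the realistic default) or `"tone"` (pure sinusoid at
#'   `freq`, used for spectral-placement checks).
#' @param freq Tone frequency in Hz, only for `type = "tone"`.
#' @return A `band_effect` list, used in [synth_config()]'s `band_effects`.
#' @export
band_effect <- function(band = "alpha", channels = posterior_channels(),
                        amplitude = 1, low_gain = 1, high_gain = 3,
                        type = c("narrowband", "tone"), freq = NULL) {
  type <- match.arg(type)
  if (low_gain <= 0 || high_gain <= 0)
    stop("class gain multipliers must be positive", call. = FALSE)
  if (type == "tone" && is.null(freq))
    stop("tone components need a frequency", call. = FALSE)
  structure(list(band = band, channels = channels, amplitude = amplitude,
                 low_gain = low_gain, high_gain = high_gain,
                 type = type, freq = freq),
            class = "band_effect")
}

#' Posterior channel subset used by the default alpha effect
#' @return Character vector of 8 parieto-occipital 10-20 labels.
#' @export
posterior_channels <- function() {
  c("O1", "Oz", "O2", "PO3", "PO4", "P3", "Pz", "P4")
}

#' Configuration of the synthetic EEG generator
#'
#' Defaults reproduce the standard affective-computing recording layout:
#' 40 trials of 63 s (3 s pre-stimulus baseline) from 32 channels at
#' 128 Hz, with one coherent narrowband alpha carrier on posterior
#' channels whose amplitude is three times larger for the high latent
#' class than for the low class.
#'
#' @param n_trials Trials per subject.
#' @param n_channels Number of EEG channels (the first `n_channels` of
#'   [deap_channels()]).
#' @param trial_seconds Total trial duration including baseline.
#' @param baseline_seconds Pre-stimulus baseline duration; the baseline is
#'   class-independent background noise.
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param band_effects List of [band_effect()] components.
#' @param noise_sd Standard deviation of the AR(1) background noise.
#' @param ar_phi AR(1) coefficient of the background noise coloring.
#' @param scheme [band_scheme()] supplying band edges for narrowband
#'   carriers.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(n_trials = 40, n_channels = 32, trial_seconds = 63,
                         baseline_seconds = 3, fs = 128,
                         band_effects = list(band_effect()),
                         noise_sd = 1, ar_phi = 0.6,
                         scheme = band_scheme(), seed = 1L) {
  cfg <- structure(
    list(n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
         trial_seconds = trial_seconds, baseline_seconds = baseline_seconds,
         fs = fs, band_effects = band_effects, noise_sd = noise_sd,
         ar_phi = ar_phi, scheme = scheme, seed = as.integer(seed)),
    class = "synth_config")
  if (cfg$trial_seconds <= cfg$baseline_seconds)
    stop("trial_seconds must exceed baseline_seconds", call. = FALSE)
  hi <- max(vapply(cfg$scheme$bands, `[`, numeric(1), 2L))
  if (cfg$fs <= 2 * hi)
    stop(sprintf("fs must exceed twice the highest band edge (%g Hz)", hi),
         call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  chn <- deap_channels()[seq_len(cfg$n_channels)]
  for (ef in cfg$band_effects) {
    if (!inherits(ef, "band_effect")) stop("band_effects must be band_effect objects", call. = FALSE)
    if (ef$type == "narrowband" && !ef$band %in% names(cfg$scheme$bands))
      stop("unknown band in band_effect: ", ef$band, call. = FALSE)
    missing <- setdiff(ef$channels, chn)
    if (length(missing))
      stop("band_effect channels not in montage: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg
}

# AR(1)-colored Gaussian noise over a [rows x time] matrix (one independent
# filter state per row), scaled so the stationary sd equals `sd`. The
# recursion runs across columns so each step is one vectorized update.
colored_noise_rows <- function(n_row, n_time, phi, sd) {
  x <- matrix(stats::rnorm(n_row * n_time), n_row, n_time)
  if (phi != 0) {
    ar1_filter_rows(x, phi) * (sd * sqrt(1 - phi^2))
  } else {
    x * sd
  }
}

# Unit-sd narrowband carrier: white noise restricted to [low, high) Hz by a
# brick-wall mask in the frequency domain.
narrowband_carrier <- function(n, band_lohi, fs) {
  freq <- (seq_len(n) - 1L) * fs / n
  alias <- pmin(freq, fs - freq)
  keep <- alias >= band_lohi[1] & alias < band_lohi[2]
  z <- stats::fft(stats::rnorm(n))
  z[!keep] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic subject recording
#'
#' Each trial draws a balanced Bernoulli latent class; ratings for all four
#' dimensions are drawn uniformly from \[6, 9\] (high) or \[1, 4\] (low) so
#' that binarization at 5 recovers the latent class exactly. The signal is
#' AR(1) background noise plus the configured class-dependent carriers,
#' which start after the baseline.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Subject identifier.
#' @param seed Overrides `cfg$seed` (used by [generate_cohort()] to derive
#'   per-subject seeds).
#' @return An [eeg_recording()] with attribute `latent_class`
#'   (integer 0/1 per trial).
#' @export
#' @examples
#' cfg <- synth_config(n_trials = 2, trial_seconds = 9)
#' rec <- generate_recording(cfg, "s01")
#' dim(rec$signal)
generate_recording <- function(cfg, subject_id = "s01", seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  n_samp <- round(cfg$trial_seconds * cfg$fs)
  n_base <- round(cfg$baseline_seconds * cfg$fs)
  chn <- deap_channels()[seq_len(cfg$n_channels)]
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  cls <- as.integer(stats::runif(cfg$n_trials) < 0.5)
  ratings <- matrix(0, cfg$n_trials, 4L,
                    dimnames = list(NULL, rating_dims()))
  ratings[] <- stats::runif(cfg$n_trials * 4L, 1, 4)
  hi <- cls == 1L
  ratings[hi, ] <- stats::runif(sum(hi) * 4L, 6, 9)
  post <- (n_base + 1L):n_samp
  t_post <- (seq_along(post) - 1L) / cfg$fs
  # rows = (channel within trial), columns = time; trials stay independent
  x <- colored_noise_rows(cfg$n_channels * cfg$n_trials, n_samp,
                          cfg$ar_phi, cfg$noise_sd)
  for (tr in seq_len(cfg$n_trials)) {
    for (ef in cfg$band_effects) {
      gain <- ef$amplitude * if (cls[tr] == 1L) ef$high_gain else ef$low_gain
      carrier <- if (ef$type == "tone") {
        sin(2 * pi * ef$freq * t_post + stats::runif(1, 0, 2 * pi))
      } else {
        narrowband_carrier(length(post), cfg$scheme$bands[[ef$band]], cfg$fs)
      }
      ci <- (tr - 1L) * cfg$n_channels + match(ef$channels, chn)
      x[ci, post] <- x[ci, post, drop = FALSE] +
        rep(gain * carrier, each = length(ci))
    }
  }
  sig <- aperm(array(x, c(cfg$n_channels, cfg$n_trials, n_samp)),
               c(2L, 1L, 3L))
  rec <- eeg_recording(subject_id, sig, cfg$fs, chn, ratings)
  attr(rec, "latent_class") <- cls
  rec
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a cohort of synthetic subjects
#'
#' Applies [generate_recording()] with per-subject derived seeds, so
#' subjects are distinct but the cohort is reproducible from `cfg$seed`.
#'
#' @inheritParams generate_recording
#' @param n_subjects Number of subjects.
#' @return List of [eeg_recording()] objects named `s01, s02, ...`.
#' @export
generate_cohort <- function(cfg, n_subjects = 32) {
  ids <- sprintf("s%02d", seq_len(n_subjects))
  out <- lapply(seq_len(n_subjects), function(i)
    generate_recording(cfg, ids[i], seed = (cfg$seed + 7919L * i) %% .Machine$integer.max))
  names(out) <- ids
  out
}
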