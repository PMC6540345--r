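test_that("band scheme defaults and validation", {
  sch <- band_scheme()
  expect_identical(sch$names, c("theta", "alpha", "beta", "gamma"))
  expect_identical(sch$bands$alpha, c(8, 15))
  expect_error(band_scheme(a = c(4, 10), b = c(8, 20)), "overlap")
  expect_error(band_scheme(a = c(10, 4)), "low < high")
})

test_that("feature layout is channel-major band-minor with 32 x 4 columns", {
  rec <- make_recording(n_ch = 32, n_sec = 6, seed = 3)
  tab <- feature_table(segment_recording(rec))
  expect_identical(ncol(tab$raw), 128L)
  expect_identical(colnames(tab$raw)[1:5],
                   c("Fp1.theta", "Fp1.alpha", "Fp1.beta", "Fp1.gamma",
                     "AF3.theta"))
  expect_true(all(tab$raw >= 0))
})

test_that("welch estimator matches a brute-force DFT periodogram", {
  # single full-length window: Welch reduces to one tapered periodogram,
  # which the O(N^2) DFT sum below computes independently
  set.seed(11)
  n <- 128; fs <- 128
  x <- rnorm(n)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n) # periodic Hann
  xw <- x * w
  nf <- n / 2 + 1
  oracle <- numeric(nf)
  for (k in seq_len(nf)) {
    re <- sum(xw * cos(2 * pi * (k - 1) * (0:(n - 1)) / n))
    im <- sum(xw * sin(2 * pi * (k - 1) * (0:(n - 1)) / n))
    oracle[k] <- (re^2 + im^2) / (fs * sum(w^2))
  }
  oracle[2:(nf - 1)] <- 2 * oracle[2:(nf - 1)]
  est <- welch_psd(x, fs, window_samples = n)
  expect_equal(est$psd[, 1], oracle, tolerance = 1e-10)
  expect_equal(est$freq, 0:(n / 2))
})

test_that("fast batched features agree with the per-segment estimator", {
  rec <- make_recording(n_ch = 4, n_sec = 9, seed = 12)
  ss <- segment_recording(rec)
  tab <- feature_table(ss)
  for (i in c(1, 3)) {
    ref <- band_psd(matrix(ss$signal[i, , ], 4, 384), 128)
    expect_equal(unname(tab$raw[i, ]), as.vector(t(ref)), tolerance = 1e-12)
  }
})

test_that("a unit 10 Hz sinusoid dominates alpha by >= 10x on its channel", {
  n <- 384
  seg <- rbind(sin(2 * pi * 10 * (0:(n - 1)) / 128),
               rep(0, n))
  p <- band_psd(seg, fs = 128)
  expect_gte(p[1, "alpha"], 10 * p[1, "theta"])
  expect_gte(p[1, "alpha"], 10 * p[1, "beta"])
  expect_gte(p[1, "alpha"], 10 * p[1, "gamma"])
  expect_equal(unname(p[2, ]), rep(0, 4)) # null signal -> zero features
})

test_that("white-noise band means are flat within three standard errors", {
  set.seed(21)
  n_rep <- 100
  vals <- matrix(0, n_rep, 4)
  for (i in seq_len(n_rep)) {
    seg <- matrix(rnorm(384), 1)
    vals[i, ] <- band_psd(seg, fs = 128)[1, ]
  }
  mu <- colMeans(vals)
  se <- apply(vals, 2, sd) / sqrt(n_rep)
  grand <- mean(mu)
  expect_true(all(abs(mu - grand) <= 3 * se))
})

test_that("band edges above Nyquist are refused", {
  expect_error(band_psd(matrix(0, 1, 384), fs = 64), "Nyquist")
})

test_that("normalization maps max->0, min->1, midpoint->0.5 per subject column", {
  tab <- fake_table(matrix(c(2, 4, 6), 3, 1))
  tab <- normalize_features(tab)
  expect_equal(unname(tab$normalized[, 1]), c(1, 0.5, 0))
  tab2 <- normalize_features(fake_table(matrix(c(2, 4, 6), 3, 1)),
                             orientation = "standard")
  expect_equal(unname(tab2$normalized[, 1]), c(0, 0.5, 1))
})

test_that("normalization is per subject and bounded in [0, 1]", {
  set.seed(31)
  raw <- matrix(rexp(40), 20, 2)
  subj <- rep(c("a", "b"), each = 10)
  tab <- normalize_features(fake_table(raw, subj))
  expect_true(all(tab$normalized >= 0 & tab$normalized <= 1))
  for (s in c("a", "b")) for (j in 1:2) {
    col <- tab$normalized[subj == s, j]
    expect_equal(max(col), 1)
    expect_equal(min(col), 0)
    # order reversal: largest raw value got the smallest normalized value
    expect_identical(order(raw[subj == s, j]), order(col, decreasing = TRUE))
  }
})

test_that("a degenerate constant column normalizes to zero", {
  tab <- normalize_features(fake_table(matrix(3, 4, 1)))
  expect_identical(unname(tab$normalized[, 1]), rep(0, 4))
})

test_that("fold-safe extrema restrict to the given rows and clip", {
  raw <- matrix(c(1, 2, 3, 10), 4, 1)
  tab <- normalize_features(fake_table(raw), extrema_rows = 1:3)
  # extrema from rows 1:3 are (1, 3); row 4 would fall outside and clips
  expect_equal(unname(tab$normalized[, 1]), c(1, 0.5, 0, 0))
})

test_that("normalize_subject matches the all-subject path for one subject", {
  set.seed(41)
  raw <- matrix(runif(12), 6, 2)
  a <- normalize_features(fake_table(raw))
  b <- normalize_subject(fake_table(raw), "s01")
  expect_equal(a$normalized, b$normalized)
})
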