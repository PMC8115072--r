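# Spectral peak discovery: wavelet spectra, 1/f detrending, consensus rule.

test_that("wavelet power peaks at the planted frequency", {
  g <- make_grid(1, 8, 2)
  cmp <- wave_component(6, 0, 10, amplitude = 10)
  rec <- synthesize(g, list(cmp), noise_sd = 1, duration_s = 12, fs = 128,
                    seed = 1)
  sp <- wavelet_spectrum(rec, n_freqs = 80, fmin = 1, fmax = 32)
  fpk <- sp$freqs[apply(sp$power, 1, which.max)]
  expect_true(all(abs(fpk - 6) < 0.5))
  # independent oracle: periodogram of channel 1 peaks at the same bin
  pg <- stats::spec.pgram(rec$data[1, ], plot = FALSE, taper = 0)
  f_oracle <- pg$freq[which.max(pg$spec)] * 128
  expect_lt(abs(f_oracle - 6), 0.5)
})

test_that("default frequency grid is 211 points over 1-32 Hz", {
  g <- make_grid(1, 2, 2)
  rec <- synthesize(g, list(), noise_sd = 1, duration_s = 2, fs = 128,
                    seed = 1)
  sp <- wavelet_spectrum(rec)
  expect_equal(length(sp$freqs), 211)
  expect_equal(sp$freqs[1], 1)
  expect_equal(sp$freqs[211], 32)
  # 42 voices per octave: 5 octaves span 211 points
  expect_equal(log2(sp$freqs[43] / sp$freqs[1]), 1, tolerance = 1e-9)
})

test_that("detrending removes an exact power law and flags a planted bump", {
  freqs <- exp(seq(log(1), log(32), length.out = 120))
  spectra <- structure(list(
    freqs = freqs,
    power = rbind(2 * freqs^-2,
                  2 * freqs^-2 * (1 + 4 * exp(-(freqs - 6)^2 / 0.5))),
    channels = 1:2, adjusted_z = NULL), class = "channel_spectra")
  sc <- detrend_and_score(spectra)
  # pure power law: flat residual
  expect_lt(max(abs(sc$adjusted_z[1, ])), 0.1)
  # bump: local maximum above 1 SD near 6 Hz
  i6 <- which.min(abs(freqs - 6))
  expect_gt(max(sc$adjusted_z[2, (i6 - 3):(i6 + 3)]), 1)
  # z-score identity per channel
  expect_equal(rowMeans(sc$adjusted_z), c(0, 0), tolerance = 1e-12)
  expect_equal(sd(sc$adjusted_z[2, ]), 1, tolerance = 1e-12)
  bad <- spectra; bad$power[1, 3] <- 0
  expect_error(detrend_and_score(bad), "positive")
})

test_that("consensus rule: enough channels agree, few channels do not", {
  set.seed(9)
  freqs <- exp(seq(log(1), log(32), length.out = 150))
  # wavelet spectra are smooth in frequency: use correlated log-noise
  mk_power <- function(bump_at = NULL) {
    e <- as.numeric(stats::filter(rnorm(length(freqs), 0, 0.3),
                                  rep(1 / 15, 15), circular = TRUE))
    p <- 2 * freqs^-2 * exp(e)
    if (!is.null(bump_at))
      p <- p * (1 + 4 * exp(-(freqs - bump_at)^2 / 0.5))
    p
  }
  # 20 of 32 channels share a 6 Hz bump
  pw <- rbind(t(replicate(20, mk_power(6))), t(replicate(12, mk_power())))
  sp <- structure(list(freqs = freqs, power = pw, channels = 1:32,
                       adjusted_z = NULL), class = "channel_spectra")
  pk <- find_consensus_peaks(detrend_and_score(sp))
  expect_gte(nrow(pk), 1)
  expect_lt(abs(pk$center_freq[1] - 6), 0.5)
  expect_gte(pk$n_channels[1], 20)

  # bump on only 3 channels (others featureless): below the 5-channel rule
  pw3 <- rbind(t(replicate(3, mk_power(6))),
               t(replicate(29, 2 * freqs^-2)))
  sp3 <- structure(list(freqs = freqs, power = pw3, channels = 1:32,
                        adjusted_z = NULL), class = "channel_spectra")
  pk3 <- find_consensus_peaks(detrend_and_score(sp3))
  expect_equal(nrow(pk3), 0)

  # two well-separated bumps on all channels: two consensus peaks
  pw2 <- t(replicate(32, mk_power() *
                       (1 + 4 * exp(-(freqs - 3)^2 / 0.3) +
                          4 * exp(-(freqs - 11)^2 / 1))))
  sp2 <- structure(list(freqs = freqs, power = pw2, channels = 1:32,
                        adjusted_z = NULL), class = "channel_spectra")
  pk2 <- find_consensus_peaks(detrend_and_score(sp2))
  expect_equal(nrow(pk2), 2)
  expect_equal(sort(round(pk2$center_freq)), c(3, 11))
})

test_that("consensus peaks emerge on the synthetic grid recording", {
  # Monte Carlo across seeds: a planted 6 Hz wave is found nearly always
  hits <- vapply(1:10, function(s) {
    rec <- bidir_recording(duration_s = 10, fs = 128, seed = s, noise_sd = 2)
    pk <- find_consensus_peaks(detrend_and_score(
      wavelet_spectrum(rec, n_freqs = 120)))
    nrow(pk) >= 1 && any(abs(pk$center_freq - 6) < 0.5)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("planted peaks carry far larger channel support than chance clusters", {
  # Per-channel z-scored residuals always contain some local maxima above
  # 1 SD (unit SD by construction), and a 2 Hz window is wide in
  # log-frequency at the low end, so aperiodic-only recordings can produce
  # small chance clusters. The discriminating signature of a genuine
  # oscillation is near-unanimous channel support.
  g <- std_grid()
  planted <- vapply(1:5, function(s) {
    rec <- bidir_recording(duration_s = 10, fs = 128, seed = s, noise_sd = 2)
    pk <- find_consensus_peaks(detrend_and_score(
      wavelet_spectrum(rec, n_freqs = 120)))
    max(0L, pk$n_channels[abs(pk$center_freq - 6) < 1])
  }, integer(1))
  chance <- vapply(1:5, function(s) {
    rec <- synthesize(g, list(), noise_sd = 2, duration_s = 10, fs = 128,
                      seed = 100 + s)
    pk <- find_consensus_peaks(detrend_and_score(
      wavelet_spectrum(rec, n_freqs = 120)))
    if (nrow(pk)) max(pk$n_channels) else 0L
  }, integer(1))
  expect_true(all(planted >= 30))
  expect_gt(min(planted), max(chance))
})

test_that("adjusted z-scores and peaks are scale invariant; threshold monotone", {
  rec <- bidir_recording(duration_s = 8, fs = 128, seed = 12)
  sp1 <- detrend_and_score(wavelet_spectrum(rec, n_freqs = 100))
  rec2 <- rec; rec2$data <- rec$data * 37
  sp2 <- detrend_and_score(wavelet_spectrum(rec2, n_freqs = 100))
  expect_equal(sp1$adjusted_z, sp2$adjusted_z, tolerance = 1e-9)
  # peak count non-increasing in the z threshold
  n_pk <- vapply(c(0.5, 1, 2, 4), function(zt)
    nrow(find_consensus_peaks(sp1, z_thresh = zt, min_channels = 1)),
    numeric(1))
  expect_true(all(diff(n_pk) <= 0))
})
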