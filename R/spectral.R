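# Oscillation-peak discovery: Morlet wavelet spectra, robust 1/f detrending,
# z-scored peak detection, and cross-channel consensus.

# Analytic Morlet mother wavelet in the frequency domain, L1-normalized so a
# unit-amplitude sinusoid yields unit wavelet magnitude at its own frequency.
# omega0 = 6 (standard trade-off; makes scale ~ omega0 / (2 pi f)).
morlet_filter <- function(omega, scale, omega0 = 6) {
  h <- numeric(length(omega))
  pos <- omega > 0
  h[pos] <- 2 * exp(-(scale * omega[pos] - omega0)^2 / 2)
  h
}

#' Morlet wavelet power spectra per channel
#'
#' Continuous Morlet wavelet transform of each usable channel at
#' logarithmically spaced frequencies, time-averaged into one power spectrum
#' per channel. Samples inside annotated artifact intervals are excluded
#' from the time average. The default frequency grid (211 points over
#' 1-32 Hz) corresponds to 42 voices per octave.
#'
#' @param rec an \code{lfp_recording} with \code{fmax < fs / 2}.
#' @param n_freqs number of log-spaced analysis frequencies.
#' @param fmin,fmax frequency band, Hz.
#' @return a \code{channel_spectra} object: list with \code{freqs} (Hz),
#'   \code{power} (channels x freqs matrix of time-mean wavelet power),
#'   \code{channels} (electrode indices of the rows), and \code{adjusted_z}
#'   (NULL until \code{\link{detrend_and_score}} is applied).
#' @export
wavelet_spectrum <- function(rec, n_freqs = 211, fmin = 1, fmax = 32) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (fmax >= rec$fs / 2)
    stop("wavelet_spectrum: fmax must be below the Nyquist frequency")
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  chans <- usable_electrodes(rec$geometry)
  n <- ncol(rec$data)
  omega <- 2 * pi * rec$fs * c(seq(0, floor(n / 2)),
                               seq(floor(n / 2) + 1, n - 1) - n) / n
  scales <- 6 / (2 * pi * freqs)
  good <- !annotation_mask(rec$annotations$artifact, n, rec$fs)
  all_good <- all(good)
  power <- matrix(NA_real_, length(chans), n_freqs)
  for (ci in seq_along(chans)) {
    X <- stats::fft(rec$data[chans[ci], ])
    for (fi in seq_len(n_freqs)) {
      H <- morlet_filter(omega, scales[fi])
      if (all_good) {
        # Parseval: time-mean |W|^2 without the inverse transform
        power[ci, fi] <- sum(Mod(X)^2 * H^2) / n^2
      } else {
        w <- stats::fft(X * H, inverse = TRUE) / n
        power[ci, fi] <- mean(Mod(w[good])^2)
      }
    }
  }
  structure(list(freqs = freqs, power = power, channels = chans,
                 adjusted_z = NULL),
            class = "channel_spectra")
}

# Logical mask of samples covered by annotation intervals.
annotation_mask <- function(iv, n, fs) {
  m <- logical(n)
  if (is.null(iv) || nrow(iv) == 0) return(m)
  for (j in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv$start_s[j] * fs) + 1L)
    i1 <- min(n, ceiling(iv$end_s[j] * fs))
    if (i1 >= i0) m[i0:i1] <- TRUE
  }
  m
}

#' Remove the aperiodic 1/f trend and z-score the residual spectra
#'
#' Fits a robust straight line (iteratively reweighted least squares with
#' bisquare weights) to each channel's log power vs log frequency,
#' subtracts it, and z-scores the residuals within channel. Narrowband
#' oscillation peaks survive as positive excursions of the adjusted z-score;
#' the power-law background is removed.
#'
#' @param spectra a \code{channel_spectra} from \code{\link{wavelet_spectrum}}.
#' @return the same object with \code{adjusted_z} filled in
#'   (channels x freqs; zero mean, unit SD per channel).
#' @export
detrend_and_score <- function(spectra) {
  stopifnot(inherits(spectra, "channel_spectra"))
  if (any(spectra$power <= 0, na.rm = TRUE))
    stop("detrend_and_score: power must be positive")
  lf <- log10(spectra$freqs)
  z <- spectra$power
  for (ci in seq_len(nrow(z))) {
    lp <- log10(spectra$power[ci, ])
    fit <- suppressWarnings(
      MASS::rlm(lp ~ lf, psi = MASS::psi.bisquare, maxit = 100))
    r <- lp - stats::fitted(fit)
    s <- stats::sd(r)
    # an exactly linear spectrum leaves only numerical noise: no structure
    z[ci, ] <- if (s < 1e-8) 0 else (r - mean(r)) / s
  }
  spectra$adjusted_z <- z
  spectra
}

# Local maxima of a vector: strictly above the left neighbor and at least as
# high as the right one, so a flat plateau reports its lowest-index point.
local_maxima <- function(z) {
  n <- length(z)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[z[i] > z[i - 1] & z[i] >= z[i + 1]]
}

#' Find consensus oscillation peaks across channels
#'
#' Per-channel peaks are local maxima of the adjusted z-score above
#' \code{z_thresh}. Peaks are clustered greedily by frequency: the strongest
#' unassigned peak seeds a cluster that absorbs each channel's nearest peak
#' within \code{bandwidth / 2} Hz (total span \code{bandwidth}); clusters
#' backed by at least \code{min_channels} distinct channels become consensus
#' peaks whose center is the mean of the member peak frequencies.
#'
#' @param spectra a scored \code{channel_spectra}
#'   (\code{\link{detrend_and_score}} applied).
#' @param z_thresh peak threshold in SD units (default 1).
#' @param bandwidth maximum frequency span of a cluster, Hz (default 2).
#' @param min_channels minimum distinct channels per consensus peak
#'   (default 5).
#' @return data.frame with \code{center_freq}, \code{n_channels}, and
#'   list-columns \code{member_channels}, \code{member_freqs}; zero rows if
#'   no consensus emerges.
#' @export
find_consensus_peaks <- function(spectra, z_thresh = 1, bandwidth = 2,
                                 min_channels = 5) {
  stopifnot(inherits(spectra, "channel_spectra"))
  if (is.null(spectra$adjusted_z))
    stop("find_consensus_peaks: run detrend_and_score() first")
  peaks <- do.call(rbind, lapply(seq_len(nrow(spectra$adjusted_z)), function(ci) {
    z <- spectra$adjusted_z[ci, ]
    idx <- local_maxima(z)
    idx <- idx[z[idx] > z_thresh]
    if (!length(idx)) return(NULL)
    data.frame(channel = spectra$channels[ci], freq = spectra$freqs[idx],
               z = z[idx])
  }))
  out <- data.frame(center_freq = numeric(0), n_channels = integer(0))
  out$member_channels <- list(); out$member_freqs <- list()
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  peaks <- peaks[order(-peaks$z), ]
  assigned <- rep(FALSE, nrow(peaks))
  clusters <- list()
  repeat {
    open <- which(!assigned)
    if (!length(open)) break
    seed <- open[1]
    f0 <- peaks$freq[seed]
    near <- open[abs(peaks$freq[open] - f0) <= bandwidth / 2]
    # one peak per channel: keep the closest-in-frequency candidate
    near <- near[order(abs(peaks$freq[near] - f0))]
    keep <- near[!duplicated(peaks$channel[near])]
    assigned[near] <- TRUE
    clusters[[length(clusters) + 1L]] <- peaks[keep, , drop = FALSE]
  }
  clusters <- Filter(function(cl) nrow(cl) >= min_channels, clusters)
  if (!length(clusters)) return(out)
  out <- data.frame(
    center_freq = vapply(clusters, function(cl) mean(cl$freq), numeric(1)),
    n_channels = vapply(clusters, nrow, integer(1)))
  out$member_channels <- lapply(clusters, function(cl) cl$channel)
  out$member_freqs <- lapply(clusters, function(cl) cl$freq)
  out[order(-out$n_channels, out$center_freq), , drop = FALSE]
}
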