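# Narrowband analytic signal extraction around an oscillation peak:
# zero-phase band-pass, Hilbert transform, downsampling to the analysis
# rate, amplitude gating for fragmented-oscillation periods.

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Extract the analytic band around a center frequency
#'
#' Zero-phase Butterworth band-pass at \code{center_freq +/- bandwidth/2}
#' (default +/- 1.5 Hz), analytic amplitude and phase per channel via the
#' Hilbert transform, then decimation to the analysis rate
#' \code{fs_analysis}. The band-pass doubles as the anti-alias filter: the
#' upper band edge must stay below \code{fs_analysis / 2}. Amplitude is
#' z-scored within channel across the whole block.
#'
#' Timepoint validity gating: the raw analytic amplitude is averaged across
#' channels, timepoints in the lowest \code{amp_percentile} percent are
#' dropped, and a surviving timepoint is kept only if its contiguous
#' above-threshold run lasts at least \code{min_cycles} oscillation cycles.
#'
#' @param rec an \code{lfp_recording}.
#' @param center_freq center frequency, Hz (must exceed
#'   \code{bandwidth / 2}).
#' @param fs_analysis analysis sampling rate, Hz (default 30; use 100 for
#'   trial-locked analyses).
#' @param bandwidth full passband width, Hz (default 3).
#' @param amp_percentile percentage of lowest-amplitude timepoints to
#'   exclude (default 10).
#' @param min_cycles minimum run length in cycles (default 3).
#' @param filter_order Butterworth section order (default 3, i.e. a
#'   6th-order band-pass applied forward and backward).
#' @return an \code{analytic_band}: list with \code{center_freq},
#'   \code{bandwidth}, \code{amplitude} (channels x timepoints, z-scored),
#'   \code{amplitude_raw}, \code{phase} (radians in (-pi, pi]),
#'   \code{fs_analysis}, \code{times} (s), \code{valid_mask},
#'   \code{channels}, \code{geometry}.
#' @export
extract_band <- function(rec, center_freq, fs_analysis = 30, bandwidth = 3,
                         amp_percentile = 10, min_cycles = 3,
                         filter_order = 3) {
  stopifnot(inherits(rec, "lfp_recording"))
  lo <- center_freq - bandwidth / 2
  hi <- center_freq + bandwidth / 2
  if (lo <= 0) stop("extract_band: lower band edge must be > 0 Hz")
  if (hi >= rec$fs / 2) stop("extract_band: band outside recording Nyquist")
  if (fs_analysis <= 2 * center_freq)
    stop("extract_band: fs_analysis must exceed twice the center frequency")
  chans <- usable_electrodes(rec$geometry)
  n <- ncol(rec$data)
  bf <- signal::butter(filter_order, c(lo, hi) / (rec$fs / 2), type = "pass")
  # decimate the complex analytic signal: band content sits below the new
  # Nyquist, so index subsampling after the band-pass is alias-free
  idx <- round(seq(1, n, by = rec$fs / fs_analysis))
  idx <- idx[idx <= n]
  amp <- phs <- matrix(NA_real_, length(chans), length(idx))
  for (ci in seq_along(chans)) {
    xf <- signal::filtfilt(bf, rec$data[chans[ci], ])
    a <- analytic_signal(xf)[idx]
    amp[ci, ] <- Mod(a)
    phs[ci, ] <- Arg(a)
  }
  phs <- wrap_pi(phs)
  amp_z <- t(scale(t(amp)))
  # gating on the channel-mean raw amplitude
  mean_amp <- colMeans(amp)
  thr <- stats::quantile(mean_amp, amp_percentile / 100)
  above <- mean_amp > thr
  valid <- above & run_length_ok(above, min_cycles / center_freq * fs_analysis)
  # artifact intervals never contribute analysis timepoints
  tms <- (idx - 1) / rec$fs
  art <- rec$annotations$artifact
  if (!is.null(art) && nrow(art) > 0) {
    for (j in seq_len(nrow(art)))
      valid[tms >= art$start_s[j] & tms <= art$end_s[j]] <- FALSE
  }
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amp_z, amplitude_raw = amp, phase = phs,
                 fs_analysis = fs_analysis, times = tms,
                 valid_mask = valid, channels = chans,
                 geometry = rec$geometry),
            class = "analytic_band")
}

# TRUE where the surrounding contiguous TRUE-run of `above` has length >=
# min_len samples.
run_length_ok <- function(above, min_len) {
  r <- rle(above)
  rep(r$values & r$lengths >= min_len, r$lengths)
}

#' @export
print.analytic_band <- function(x, ...) {
  cat(sprintf(
    "<analytic_band> %.2f Hz (+/- %.2f), %d channels x %d timepoints @ %g Hz, %d valid\n",
    x$center_freq, x$bandwidth / 2, nrow(x$phase), ncol(x$phase),
    x$fs_analysis, sum(x$valid_mask)))
  invisible(x)
}
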