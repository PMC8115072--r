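# Readers/writers, artifact screening, configuration, and end-to-end
# orchestration.

#' Analysis configuration with study defaults
#'
#' Collects every tunable of the pipeline in one list. Defaults: 1-32 Hz
#' spectral band with 211 log-spaced wavelet frequencies, 30 Hz analysis
#' rate (100 Hz for trial-locked analyses), 3 Hz band-pass width, lowest
#' 10% amplitude exclusion with a 3-cycle minimum, 200 electrode-shuffle
#' iterations at a 99% one-sided validity level, 10-degree direction bins
#' with 60-degree circular smoothing, 25% bimodality rule, 45-degree angle
#' split, and 10000 label-shuffle iterations for the classifier.
#'
#' @param ... named overrides of any default.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band_hz = c(1, 32), n_wavelet_freqs = 211,
    analysis_fs = 30, trial_fs = 100,
    bandwidth_hz = 3, amp_percentile = 10, min_cycles = 3,
    null_iters = 200, ci_percent = 99,
    bins_deg = 10, smooth_deg = 60, bimodal_frac = 0.25,
    split_halfwidth_deg = 45, svm_null_iters = 10000,
    peak_z_thresh = 1, peak_bandwidth_hz = 2, peak_min_channels = 5,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$ci_percent > 50, cfg$ci_percent < 100,
            all(unlist(cfg[c("analysis_fs", "trial_fs", "bandwidth_hz",
                             "amp_percentile", "min_cycles", "bins_deg",
                             "smooth_deg")]) > 0))
  structure(cfg, class = "pipeline_config")
}

#' Write a recording to disk
#'
#' Native container: the channels x samples matrix as little-endian
#' float64 (\code{<path>.dat}) plus a JSON sidecar (\code{<path>.json})
#' holding the sampling rate, electrode coordinates, bad channels, and
#' annotations. Round-trips bit-exactly.
#'
#' @param rec an \code{lfp_recording}.
#' @param path output path stem (without extension).
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  sidecar <- list(
    fs = rec$fs, n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    coords_mm = unname(as.matrix(rec$geometry$coords)),
    pitch_mm = rec$geometry$pitch,
    n_rows = rec$geometry$n_rows, n_cols = rec$geometry$n_cols,
    bad_channels = rec$geometry$bad_channels,
    annotations = lapply(rec$annotations, function(a)
      if (is.data.frame(a)) a else NULL))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' @param path path stem used when writing.
#' @return an \code{lfp_recording}.
#' @export
read_recording <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(sc$fs)) stop("read_recording: sidecar missing sampling rate")
  n <- sc$n_channels * sc$n_samples
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(v) != n)
    stop("read_recording: data size does not match sidecar dimensions")
  coords <- matrix(unlist(sc$coords_mm), ncol = 2,
                   byrow = !is.matrix(sc$coords_mm))
  if (is.matrix(sc$coords_mm)) coords <- sc$coords_mm
  colnames(coords) <- c("x", "y")
  geom <- structure(list(coords = coords, pitch = sc$pitch_mm,
                         n_rows = as.integer(sc$n_rows %||% NA),
                         n_cols = as.integer(sc$n_cols %||% NA),
                         bad_channels = as.integer(sc$bad_channels)),
                    class = "grid_geometry")
  ann <- lapply(sc$annotations, function(a)
    if (!is.null(a) && length(a)) as.data.frame(a) else
      data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (is.null(ann$artifact))
    ann$artifact <- data.frame(start_s = numeric(0), end_s = numeric(0))
  structure(list(data = matrix(v, sc$n_channels, sc$n_samples),
                 fs = sc$fs, geometry = geom, annotations = ann,
                 truth = NULL),
            class = "lfp_recording")
}

#' Line-length artifact screening
#'
#' Line length -- the sum of absolute sample-to-sample differences inside a
#' sliding window -- is a standard feature for detecting electrical
#' artifacts and epileptiform discharges. Windows in which any channel's
#' line length exceeds its own median plus \code{threshold_mads} median
#' absolute deviations are flagged; flagged windows are merged into
#' intervals and recorded as artifact annotations so they are excluded from
#' all downstream statistics.
#'
#' @param rec an \code{lfp_recording}.
#' @param window_s sliding-window length, seconds (default 1).
#' @param threshold_mads MAD multiplier above the per-channel median
#'   (default 5).
#' @return the recording with updated artifact annotations; the flagged
#'   intervals are also in \code{attr(,"flagged")}.
#' @export
line_length_screen <- function(rec, window_s = 1, threshold_mads = 5) {
  stopifnot(inherits(rec, "lfp_recording"), window_s > 0)
  n <- ncol(rec$data)
  w <- max(2L, round(window_s * rec$fs))
  flagged <- logical(n)
  for (ch in seq_len(nrow(rec$data))) {
    dv <- c(0, abs(diff(rec$data[ch, ])))
    # centered moving sum of |diff| over the window
    cs <- cumsum(dv)
    half <- w %/% 2
    lo <- pmax(0, seq_len(n) - half - 1)
    hi <- pmin(n, seq_len(n) + half)
    ll <- cs[hi] - c(0, cs)[lo + 1]
    med <- stats::median(ll)
    mad_ <- stats::mad(ll)
    if (mad_ == 0) next
    flagged <- flagged | (ll > med + threshold_mads * mad_)
  }
  iv <- mask_to_intervals(flagged, rec$fs)
  rec$annotations$artifact <- merge_intervals(
    rbind(rec$annotations$artifact, iv))
  attr(rec, "flagged") <- iv
  rec
}

# Convert a logical sample mask to a data.frame of time intervals.
mask_to_intervals <- function(mask, fs) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  data.frame(start_s = (starts[on] - 1) / fs, end_s = ends[on] / fs)
}

#' Run the full traveling-wave pipeline
#'
#' Artifact screening, consensus-peak discovery, then per peak frequency:
#' band extraction, plane-wave fitting with permutation nulls, direction
#' distribution and modality, angle split, and (when the distribution is
#' bidirectional) the amplitude-topography direction classifier; with
#' events, the event-locked DC analysis at the trial rate.
#'
#' @param rec an \code{lfp_recording}.
#' @param config a \code{\link{pipeline_config}}.
#' @param events optional event data.frame (\code{time_s}, \code{label},
#'   \code{rt_s}) for the DC stage.
#' @param screen_artifacts run \code{\link{line_length_screen}} first
#'   (default TRUE).
#' @param classifier_null_iters label-shuffle iterations (default from
#'   config).
#' @return a \code{wave_report}: list with \code{peaks}, and per-frequency
#'   entries each holding \code{band}, \code{fits}, \code{distribution},
#'   \code{split}, \code{classifier}, \code{dc}; plus the \code{config}.
#' @export
run_pipeline <- function(rec, config = pipeline_config(), events = NULL,
                         screen_artifacts = TRUE,
                         classifier_null_iters = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (screen_artifacts) rec <- line_length_screen(rec)
  spectra <- detrend_and_score(wavelet_spectrum(
    rec, n_freqs = config$n_wavelet_freqs,
    fmin = config$band_hz[1], fmax = config$band_hz[2]))
  peaks <- find_consensus_peaks(
    spectra, z_thresh = config$peak_z_thresh,
    bandwidth = config$peak_bandwidth_hz,
    min_channels = config$peak_min_channels)
  results <- list()
  for (j in seq_len(nrow(peaks))) {
    f0 <- peaks$center_freq[j]
    band <- extract_band(rec, f0, fs_analysis = config$analysis_fs,
                         bandwidth = config$bandwidth_hz,
                         amp_percentile = config$amp_percentile,
                         min_cycles = config$min_cycles)
    fits <- fit_series(band, null_iters = config$null_iters,
                       ci_percent = config$ci_percent, seed = config$seed)
    dist <- build_distribution(fits$direction_deg[fits$is_valid],
                               bin_deg = config$bins_deg,
                               smooth_deg = config$smooth_deg,
                               bimodal_frac = config$bimodal_frac)
    entry <- list(center_freq = f0, band = band, fits = fits,
                  distribution = dist, split = NULL, classifier = NULL,
                  dc = NULL)
    if (dist$modality == "bidirectional") {
      entry$split <- angle_split(fits, dist$modes,
                                 half_width = config$split_halfwidth_deg)
      cls <- try(build_dataset(band, entry$split, seed = config$seed),
                 silent = TRUE)
      if (!inherits(cls, "try-error")) {
        entry$classifier <- shuffle_null(
          cls, n_iter = classifier_null_iters %||% config$svm_null_iters,
          seed = config$seed)
      }
    }
    if (!is.null(events)) {
      band_t <- extract_band(rec, f0, fs_analysis = config$trial_fs,
                             bandwidth = config$bandwidth_hz,
                             amp_percentile = config$amp_percentile,
                             min_cycles = config$min_cycles)
      fits_t <- fit_series(band_t, null_iters = 0, seed = config$seed)
      ts <- try(epoch_trials(fits_t, events,
                             artifact = rec$annotations$artifact),
                silent = TRUE)
      if (!inherits(ts, "try-error"))
        entry$dc <- directionality_consistency(ts, seed = config$seed)
    }
    results[[sprintf("f%.2f", f0)]] <- entry
  }
  structure(list(peaks = peaks, frequencies = results, config = config),
            class = "wave_report")
}

#' @export
print.wave_report <- function(x, ...) {
  cat(sprintf("<wave_report> %d consensus peak(s)\n", nrow(x$peaks)))
  for (e in x$frequencies) {
    cat(sprintf("  %.2f Hz: %s, mode(s) %s deg, %d valid timepoints",
                e$center_freq, e$distribution$modality,
                paste(sprintf("%.0f", e$distribution$modes), collapse = "/"),
                sum(e$fits$is_valid)))
    if (!is.null(e$classifier))
      cat(sprintf("; classifier %.1f%% (null p99 %.1f%%)",
                  e$classifier$accuracy, e$classifier$null_p99))
    cat("\n")
  }
  invisible(x)
}
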