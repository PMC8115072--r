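# Event-locked directionality consistency (DC): per-timepoint circular
# average of wave directions across trials, Rayleigh significance with
# Benjamini-Hochberg FDR control, a shuffled-timepoint null band, and
# reaction-time splits.

#' Epoch a wave-fit series into event-locked trials
#'
#' Aligns the per-timepoint wave directions to task events with a window of
#' \code{window[1]} s before to \code{window[2]} s after each event. Trials
#' whose window extends beyond the recording are dropped with a warning;
#' trials overlapping an artifact interval are excluded. At least 10 trials
#' must survive.
#'
#' @param fits a \code{wave_fit_series} (typically computed at 100 Hz for
#'   trial analyses).
#' @param events event times in seconds, or a data.frame with
#'   \code{time_s}, optional \code{label} and \code{rt_s}.
#' @param window length-2: seconds before and after the event (default
#'   \code{c(2, 2)}).
#' @param rt reaction times per event, seconds (overrides
#'   \code{events$rt_s}).
#' @param artifact optional data.frame of artifact intervals
#'   (\code{start_s}, \code{end_s}); overlapping trials are excluded.
#' @param include_invalid include timepoints whose fits failed the validity
#'   screen (default TRUE; per-timepoint n is recorded downstream either
#'   way).
#' @return a \code{trial_set}: list with \code{directions} and \code{r2}
#'   (trials x timepoints), \code{times} (s relative to event),
#'   \code{reaction_times}, \code{event_times}, \code{fs},
#'   \code{n_excluded}.
#' @export
epoch_trials <- function(fits, events, window = c(2, 2), rt = NULL,
                         artifact = NULL, include_invalid = TRUE) {
  stopifnot(inherits(fits, "wave_fit_series"))
  if (is.data.frame(events)) {
    rt <- rt %||% events$rt_s
    events <- events$time_s
  }
  fs <- attr(fits, "fs_analysis")
  t0 <- fits$t[1]
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs)
  dirs <- fits$direction_deg
  if (!include_invalid) dirs[!fits$is_valid] <- NA_real_
  keep <- logical(length(events))
  rows_dir <- rows_r2 <- list()
  excl_art <- 0L
  for (j in seq_along(events)) {
    ic <- round((events[j] - t0) * fs) + 1L
    idx <- (ic - pre):(ic + post)
    if (idx[1] < 1L || idx[length(idx)] > nrow(fits)) next
    if (!is.null(artifact) && nrow(artifact) > 0) {
      w0 <- events[j] - window[1]; w1 <- events[j] + window[2]
      if (any(artifact$start_s < w1 & artifact$end_s > w0)) {
        excl_art <- excl_art + 1L
        next
      }
    }
    keep[j] <- TRUE
    rows_dir[[length(rows_dir) + 1L]] <- dirs[idx]
    rows_r2[[length(rows_r2) + 1L]] <- fits$r2[idx]
  }
  n_edge <- sum(!keep) - excl_art
  if (n_edge > 0)
    warning(sprintf("epoch_trials: %d trial(s) dropped at recording edges",
                    n_edge))
  n <- sum(keep)
  if (n < 10)
    stop("epoch_trials: fewer than 10 usable trials (n = ", n,
         "); directionality consistency cannot be assessed")
  structure(list(directions = do.call(rbind, rows_dir),
                 r2 = do.call(rbind, rows_r2),
                 times = seq(-pre, post) / fs,
                 reaction_times = if (!is.null(rt)) rt[keep] else NULL,
                 event_times = events[keep], fs = fs,
                 n_excluded = length(events) - n),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d timepoints @ %g Hz (%.1f to %.1f s)\n",
              nrow(x$directions), ncol(x$directions), x$fs,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Directionality consistency across trials
#'
#' At each event-locked timepoint, DC is the mean resultant length of the
#' per-trial wave directions: 0 for directions scattered uniformly across
#' trials, 1 when every trial's wave travels the same way. Rayleigh
#' p-values per timepoint are corrected across the window with the
#' Benjamini-Hochberg procedure. A null band is built from surrogates in
#' which each trial's direction series is circularly shifted by an
#' independent random offset (preserving within-trial autocorrelation);
#' the band pools DC values over all timepoints and surrogates.
#'
#' @param ts a \code{trial_set}.
#' @param n_surrogates shuffled-timepoint surrogates for the null band
#'   (default 200; 0 skips it).
#' @param band_percent central coverage of the null band (default 95).
#' @param seed seed for the surrogate shifts.
#' @return a \code{dc_result} data.frame: \code{t}, \code{dc},
#'   \code{mean_direction_deg}, \code{mean_r2}, \code{n}, \code{p_raw},
#'   \code{p_fdr}; the null band is in \code{attr(, "null_band")}
#'   (\code{lo}, \code{hi}).
#' @export
directionality_consistency <- function(ts, n_surrogates = 200,
                                       band_percent = 95, seed = 1) {
  stopifnot(inherits(ts, "trial_set"))
  rad <- deg2rad(ts$directions)
  dc_of <- function(m) {
    z <- exp(1i * m)
    z[is.na(m)] <- NA
    nn <- colSums(!is.na(m))
    s <- colSums(z, na.rm = TRUE)
    ifelse(nn > 0, Mod(s) / nn, NA_real_)
  }
  dc <- dc_of(rad)
  nn <- colSums(!is.na(rad))
  mean_dir <- wrap_deg(rad2deg(Arg(colSums(exp(1i * rad), na.rm = TRUE))))
  p_raw <- vapply(seq_len(ncol(rad)), function(j) {
    x <- rad[!is.na(rad[, j]), j]
    if (length(x) < 2) return(NA_real_)
    rayleigh_test(x)$p
  }, numeric(1))
  p_fdr <- fdr_correct(p_raw)
  band <- c(lo = NA_real_, hi = NA_real_)
  if (n_surrogates > 0) {
    ntp <- ncol(rad)
    pool <- with_seed(seed, {
      vals <- matrix(NA_real_, n_surrogates, ntp)
      for (s in seq_len(n_surrogates)) {
        shifts <- sample.int(ntp, nrow(rad), replace = TRUE)
        sh <- rad
        for (i in seq_len(nrow(rad)))
          sh[i, ] <- rad[i, ((seq_len(ntp) - 1 + shifts[i]) %% ntp) + 1]
        vals[s, ] <- dc_of(sh)
      }
      vals
    })
    qs <- stats::quantile(pool, c((100 - band_percent) / 200,
                                  1 - (100 - band_percent) / 200),
                          na.rm = TRUE)
    band <- c(lo = unname(qs[1]), hi = unname(qs[2]))
  }
  out <- data.frame(t = ts$times, dc = dc,
                    mean_direction_deg = mean_dir,
                    mean_r2 = colMeans(ts$r2, na.rm = TRUE),
                    n = nn, p_raw = p_raw, p_fdr = p_fdr)
  attr(out, "null_band") <- band
  class(out) <- c("dc_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' missing values are passed through.
#'
#' @param p_raw p-values in \code{[0, 1]}.
#' @return adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_raw) {
  stats::p.adjust(p_raw, method = "BH")
}

#' Median split of trials by reaction time
#'
#' Splits a trial set at the median reaction time; trials at exactly the
#' median go to the fast half.
#'
#' @param ts a \code{trial_set} with reaction times.
#' @return list with \code{fast} and \code{slow} \code{trial_set}s.
#' @export
rt_split <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  rt <- ts$reaction_times
  if (is.null(rt)) stop("rt_split: trial set has no reaction times")
  med <- stats::median(rt)
  pick <- function(sel) {
    out <- ts
    out$directions <- ts$directions[sel, , drop = FALSE]
    out$r2 <- ts$r2[sel, , drop = FALSE]
    out$reaction_times <- rt[sel]
    out$event_times <- ts$event_times[sel]
    out
  }
  list(fast = pick(rt <= med), slow = pick(rt > med))
}
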