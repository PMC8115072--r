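# Synthetic surface-LFP generator with planted traveling waves. Ground truth
# (direction, spatial frequency, regime schedule, amplitude topography) is
# known exactly, so every downstream stage can be validated without recorded
# data.

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a planted traveling-wave component
#'
#' A plane wave at a fixed temporal frequency: at electrode i with position
#' \eqn{(x_i, y_i)} the contribution is
#' \deqn{A g_i \cos(2\pi f t - k_{rad}(x_i\cos\theta + y_i\sin\theta) + \phi_0)}
#' with \eqn{k_{rad} = k \pi / 180} converting the spatial frequency from
#' degrees/mm to radians/mm. \eqn{\theta} is the direction of travel (the
#' direction of \eqn{-\nabla} phase): 0 along +x, counterclockwise positive.
#'
#' @param center_freq temporal frequency, Hz (0, 32].
#' @param direction travel direction, degrees in [0, 360).
#' @param spatial_freq spatial frequency k, degrees/mm (0, 90].
#' @param amplitude peak amplitude, microvolts.
#' @param amp_topography per-electrode gain vector (unit mean) or NULL for
#'   a flat topography.
#' @param phase0 temporal phase offset, degrees.
#' @return a \code{wave_component} list.
#' @export
wave_component <- function(center_freq, direction, spatial_freq,
                           amplitude = 10, amp_topography = NULL,
                           phase0 = 0) {
  if (center_freq <= 0 || center_freq > 32)
    stop("wave_component: center_freq must be in (0, 32] Hz")
  if (spatial_freq <= 0 || spatial_freq > 90)
    stop("wave_component: spatial_freq must be in (0, 90] degrees/mm")
  if (amplitude < 0) stop("wave_component: amplitude must be >= 0")
  structure(list(center_freq = center_freq,
                 direction = wrap_deg(direction),
                 spatial_freq = spatial_freq,
                 amplitude = amplitude,
                 amp_topography = amp_topography,
                 phase0 = wrap_deg(phase0)),
            class = "wave_component")
}

#' Direction-coupled amplitude gain map
#'
#' A unit-mean per-electrode gain that increases linearly along a given
#' direction across the grid, emulating amplitude topographies that differ
#' between propagation regimes.
#'
#' @param geometry a \code{grid_geometry}.
#' @param direction_deg direction of the gain gradient, degrees.
#' @param strength relative peak-to-trough modulation (0 = flat; 0.5 means
#'   gains span roughly 0.75..1.25).
#' @return numeric gain vector, one entry per electrode, mean 1.
#' @export
gradient_topography <- function(geometry, direction_deg, strength = 0.5) {
  a <- deg2rad(direction_deg)
  proj <- geometry$coords[, 1] * cos(a) + geometry$coords[, 2] * sin(a)
  rng <- diff(range(proj))
  if (rng == 0) return(rep(1, nrow(geometry$coords)))
  g <- 1 + strength * (proj - mean(proj)) / rng
  g / mean(g)
}

#' Define a regime schedule
#'
#' Segments say which wave components are active when (emulating switches
#' between roughly opposite propagation regimes); optional trial events add
#' task structure with post-event direction alignment.
#'
#' @param segments data.frame with \code{start_s}, \code{end_s} and
#'   \code{component} (index into the component list; a list-column of
#'   integer vectors for multiple simultaneous components). Segments must be
#'   time-ordered and non-overlapping.
#' @param trial_events optional data.frame with \code{time_s}, \code{label}
#'   (e.g. "stimulus"/"speech") and \code{rt_s} (reaction time).
#' @param align_window_s window relative to each event, seconds, inside
#'   which an aligned trial's wave adopts the task direction.
#' @param align_prob probability in [0, 1] that a trial aligns.
#' @param align_component component index imposed during aligned windows.
#' @return a \code{regime_schedule} list.
#' @export
regime_schedule <- function(segments, trial_events = NULL,
                            align_window_s = c(0.7, 1.6),
                            align_prob = 0, align_component = NA_integer_) {
  stopifnot(is.data.frame(segments),
            all(c("start_s", "end_s", "component") %in% names(segments)))
  o <- order(segments$start_s)
  segments <- segments[o, , drop = FALSE]
  if (any(segments$end_s <= segments$start_s))
    stop("regime_schedule: segments must have end_s > start_s")
  if (nrow(segments) > 1 &&
      any(segments$start_s[-1] < segments$end_s[-nrow(segments)] - 1e-9))
    stop("regime_schedule: segments overlap")
  if (align_prob < 0 || align_prob > 1)
    stop("regime_schedule: align_prob must be in [0, 1]")
  structure(list(segments = segments, trial_events = trial_events,
                 align_window_s = align_window_s, align_prob = align_prob,
                 align_component = align_component),
            class = "regime_schedule")
}

# Binary activation envelope for one component, with raised-cosine ramps at
# segment edges to avoid broadband transients.
activation_envelope <- function(schedule, comp_id, n, fs, ramp_s = 0.1) {
  env <- numeric(n)
  segs <- schedule$segments
  for (j in seq_len(nrow(segs))) {
    ids <- segs$component[[j]]
    if (comp_id %in% ids) {
      i0 <- max(1L, floor(segs$start_s[j] * fs) + 1L)
      i1 <- min(n, ceiling(segs$end_s[j] * fs))
      if (i1 >= i0) env[i0:i1] <- 1
    }
  }
  ramp <- max(1L, round(ramp_s * fs))
  if (ramp > 1L) {
    w <- (1 - cos(2 * pi * seq_len(ramp) / (ramp + 1))) / 2
    w <- w / sum(w)
    env <- stats::filter(c(rep(env[1], ramp), env, rep(env[n], ramp)),
                         w, sides = 2)
    env <- as.numeric(env[(ramp + 1):(ramp + n)])
  }
  env
}

# 1/f^exponent background: spectrally shaped white noise, scaled to unit
# SD. A low-frequency knee (default 0.3 Hz, below the analysis band) keeps
# the sub-Hz divergence from swallowing the variance budget, so the in-band
# spectrum is a clean power law.
aperiodic_noise <- function(n, fs, exponent, knee_hz = 0.3) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  X <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]   # fold to real freqs
  shape <- (1 + (freqs / knee_hz)^exponent)^(-1 / 2)
  shape[1] <- 0                                         # zero-mean output
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthesize a multichannel LFP recording
#'
#' Sums the scheduled plane-wave components on the electrode grid and adds
#' per-channel 1/f background plus white noise. With the same seed and
#' parameters the output is bit-identical.
#'
#' @param geometry a \code{grid_geometry}.
#' @param components list of \code{wave_component}s.
#' @param schedule a \code{regime_schedule}; NULL activates all components
#'   for the whole duration.
#' @param aperiodic_exponent exponent of the 1/f^a background power law
#'   (default 2).
#' @param noise_sd standard deviation of the 1/f background, microvolts;
#'   white measurement noise with SD \code{noise_sd / 50} (an
#'   amplifier-like floor well below the aperiodic background) is added on
#'   top.
#' @param duration_s recording length, seconds.
#' @param fs sampling rate, Hz (must exceed twice the highest component
#'   frequency).
#' @param seed integer seed fixing all randomness.
#' @return an \code{lfp_recording}: list with \code{data}
#'   (channels x samples, microvolts), \code{fs}, \code{geometry},
#'   \code{annotations} (artifact intervals, trial events), and
#'   \code{truth} (the planted components and schedule).
#' @export
synthesize <- function(geometry, components, schedule = NULL,
                       aperiodic_exponent = 2, noise_sd = 2,
                       duration_s = 60, fs = 512, seed = 1) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (length(components) && inherits(components, "wave_component"))
    components <- list(components)
  fmax <- if (length(components))
    max(vapply(components, `[[`, numeric(1), "center_freq")) else 0
  if (fs <= 2 * fmax)
    stop("synthesize: fs must exceed twice the highest component frequency")
  for (cm in components)
    if (cm$spatial_freq > spatial_nyquist(geometry))
      stop("synthesize: component spatial_freq beyond the grid's spatial Nyquist")
  n <- round(duration_s * fs)
  n_ch <- nrow(geometry$coords)
  if (is.null(schedule)) {
    schedule <- regime_schedule(data.frame(
      start_s = 0, end_s = duration_s,
      component = I(list(seq_along(components)))))
  }
  tt <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    # trial alignment draws (one per event), before channel noise so channel
    # count does not perturb them
    ev <- schedule$trial_events
    aligned <- logical(0)
    if (!is.null(ev) && nrow(ev) > 0 && schedule$align_prob > 0)
      aligned <- stats::runif(nrow(ev)) < schedule$align_prob

    data <- matrix(0, n_ch, n)
    for (ci in seq_along(components)) {
      cm <- components[[ci]]
      env <- activation_envelope(schedule, ci, n, fs)
      # impose task direction inside aligned trial windows
      if (length(aligned) && !is.na(schedule$align_component)) {
        for (ti in which(aligned)) {
          i0 <- max(1L, floor((ev$time_s[ti] + schedule$align_window_s[1]) * fs) + 1L)
          i1 <- min(n, ceiling((ev$time_s[ti] + schedule$align_window_s[2]) * fs))
          if (i1 >= i0)
            env[i0:i1] <- if (ci == schedule$align_component) 1 else 0
        }
      }
      gain <- cm$amp_topography %||% rep(1, n_ch)
      k_rad <- cm$spatial_freq * pi / 180
      a <- deg2rad(cm$direction)
      proj <- geometry$coords[, 1] * cos(a) + geometry$coords[, 2] * sin(a)
      tphase <- 2 * pi * cm$center_freq * tt + deg2rad(cm$phase0)
      # cos(tphase[t] - k_rad * proj[ch]), gated by the activation envelope
      phasemat <- outer(-k_rad * proj, tphase, "+")
      data <- data + cm$amplitude * outer(gain, env) * cos(phasemat)
    }
    if (noise_sd > 0) {
      for (ch in seq_len(n_ch)) {
        data[ch, ] <- data[ch, ] + noise_sd * aperiodic_noise(n, fs, aperiodic_exponent) +
          stats::rnorm(n, sd = noise_sd / 50)
      }
    }
    structure(list(data = data, fs = fs, geometry = geometry,
                   annotations = list(
                     artifact = data.frame(start_s = numeric(0),
                                           end_s = numeric(0)),
                     trial_events = ev),
                   truth = list(components = components, schedule = schedule,
                                aligned_trials = which(aligned),
                                seed = seed)),
              class = "lfp_recording")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  na <- nrow(x$annotations$artifact)
  if (na) cat(sprintf("  %d artifact interval(s)\n", na))
  invisible(x)
}

# Merge overlapping/adjacent intervals given as a 2-column structure.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[[1]]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (j in seq_len(nrow(iv))[-1]) {
    if (iv[[1]][j] <= out[[2]][nrow(out)]) {
      out[[2]][nrow(out)] <- max(out[[2]][nrow(out)], iv[[2]][j])
    } else out <- rbind(out, iv[j, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Inject artifacts into a recording
#'
#' Adds large-signature artifacts (a DC step or a high-frequency burst) over
#' the given windows on all channels and records the windows as artifact
#' annotations; overlapping windows are merged.
#'
#' @param rec an \code{lfp_recording}.
#' @param windows data.frame with \code{start_s}, \code{end_s} (within the
#'   recording).
#' @param kind "step" (default, 500 microvolt offset) or "highfreq"
#'   (80 Hz burst).
#' @param amplitude_uv artifact amplitude, microvolts.
#' @return the modified \code{lfp_recording}.
#' @export
inject_artifact <- function(rec, windows, kind = c("step", "highfreq"),
                            amplitude_uv = 500) {
  kind <- match.arg(kind)
  if (nrow(windows) == 0) return(rec)
  dur <- ncol(rec$data) / rec$fs
  if (any(windows$start_s < 0) || any(windows$end_s > dur) ||
      any(windows$end_s <= windows$start_s))
    stop("inject_artifact: windows must lie within the recording")
  for (j in seq_len(nrow(windows))) {
    i0 <- floor(windows$start_s[j] * rec$fs) + 1L
    i1 <- min(ncol(rec$data), ceiling(windows$end_s[j] * rec$fs))
    idx <- i0:i1
    add <- switch(kind,
      step = rep(amplitude_uv, length(idx)),
      highfreq = amplitude_uv * sin(2 * pi * 80 * (idx - i0) / rec$fs))
    rec$data[, idx] <- sweep(rec$data[, idx, drop = FALSE], 2, add, "+")
  }
  rec$annotations$artifact <- merge_intervals(rbind(
    rec$annotations$artifact,
    data.frame(start_s = windows$start_s, end_s = windows$end_s)))
  rec
}
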