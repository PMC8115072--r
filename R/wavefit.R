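# Circular-linear plane-wave regression. Oscillation phase at electrode
# position (x, y) is modeled as
#     phi_i = phi0 - k_rad * (x_i cos(theta) + y_i sin(theta)),
# theta the direction of travel (of -grad phase), k the spatial frequency.
# The (theta, k) lattice is searched exhaustively (1 degree x 1 degree/mm by
# default, k up to the grid's spatial Nyquist); the fit score maximized is
# the mean resultant length of the phase residuals, and goodness-of-fit is
# reported as the squared circular-circular correlation between observed
# and fitted phases.

# Precompute the (theta, k) lattice phasor matrices for a fixed electrode
# layout: one n_theta x n_ch complex matrix exp(1i * k_rad * proj) per k.
# Reused across timepoints and across null permutations.
make_lattice <- function(coords, k_max = 90, theta_step = 1, k_step = 1) {
  thetas <- seq(0, 360 - theta_step, by = theta_step)
  ks <- seq(k_step, k_max, by = k_step)
  a <- deg2rad(thetas)
  # projection of each electrode onto each candidate travel direction
  P <- cbind(cos(a), sin(a)) %*% t(coords)        # n_theta x n_ch
  W <- lapply(ks, function(k) exp(1i * (k * pi / 180) * P))
  list(thetas = thetas, ks = ks, W = W, n_ch = ncol(P))
}

# Batched lattice search over all timepoints at once. `phasors` is a
# channels x timepoints complex matrix exp(1i * phase) with NA for missing
# phases. Returns per-timepoint argmax and the complex residual resultant.
# k = 0 (spatially uniform phase) is always a candidate; ties break toward
# smaller k, then smaller theta.
plane_wave_engine <- function(phasors, coords, k_max = 90,
                              theta_step = 1, k_step = 1,
                              lattice = NULL) {
  lat <- lattice %||% make_lattice(coords, k_max, theta_step, k_step)
  n_ch <- nrow(phasors)
  nt <- ncol(phasors)
  miss <- is.na(phasors)
  phasors[miss] <- 0
  n_fin <- n_ch - colSums(miss)
  cols <- seq_len(nt)
  s0 <- colSums(phasors)                           # k = 0, theta-independent
  best_score <- Mod(s0) / n_fin
  best_theta <- rep(NA_real_, nt)
  best_k <- rep(0, nt)
  best_res <- s0
  for (j in seq_along(lat$ks)) {
    S <- lat$W[[j]] %*% phasors                    # residual = phi + k*proj
    M <- Mod(S)
    ti <- max.col(t(M), ties.method = "first")
    pick <- cbind(ti, cols)
    sc <- M[pick] / n_fin
    upd <- sc > best_score
    best_score[upd] <- sc[upd]
    best_theta[upd] <- lat$thetas[ti[upd]]
    best_k[upd] <- lat$ks[j]
    best_res[upd] <- S[pick][upd]
  }
  list(theta = best_theta, k = best_k, score = best_score,
       offset = Arg(best_res), n_finite = n_fin)
}

# Squared circular-circular correlation between observed phases (channels x
# timepoints) and the fitted plane-wave phases implied by per-timepoint
# (theta, k); vectorized across timepoints. k = 0 columns return 0.
series_r2 <- function(phase_mat, coords, theta, k) {
  nt <- ncol(phase_mat)
  a <- deg2rad(theta)
  kr <- k * pi / 180
  psi <- -(outer(coords[, 1], kr * cos(a)) + outer(coords[, 2], kr * sin(a)))
  zf <- exp(1i * phase_mat)
  zf[is.na(zf)] <- 0
  mu_obs <- Arg(colSums(zf))
  zp <- exp(1i * psi)
  zp[is.na(phase_mat)] <- 0
  mu_fit <- Arg(colSums(zp))
  so <- sin(sweep(phase_mat, 2, mu_obs))
  sf <- sin(sweep(psi, 2, mu_fit))
  so[is.na(phase_mat)] <- 0
  sf[is.na(phase_mat)] <- 0
  num <- colSums(so * sf)
  den <- sqrt(colSums(so^2) * colSums(sf^2))
  r <- ifelse(den < .Machine$double.eps | is.na(k) | k == 0, 0, num / den)
  r^2
}

#' Fit a plane wave to one timepoint of phases
#'
#' Exhaustive search over travel directions (1 degree steps over 360
#' degrees) and spatial frequencies (1 degree/mm steps up to the grid's
#' spatial Nyquist, 90 degrees/mm at 2 mm pitch). The maximized score is
#' the mean resultant length of the phase residuals; ties break toward
#' smaller k, then smaller theta. A spatially uniform phase field returns
#' k = 0 with undefined direction and R-squared 0.
#'
#' @param phases per-electrode phase in radians (NA allowed for missing).
#' @param geometry a \code{grid_geometry} with matching electrode count.
#' @param center_freq optional temporal frequency, Hz; enables the speed
#'   column.
#' @param k_max spatial-frequency ceiling, degrees/mm (default: the grid's
#'   spatial Nyquist).
#' @param theta_step,k_step lattice resolution (degrees, degrees/mm).
#' @param min_electrodes minimum number of finite-phase usable electrodes
#'   (default 8; reduced-layout analyses may lower it to 6).
#' @return a one-row data.frame: \code{direction_deg}, \code{k_deg_mm},
#'   \code{phase_offset_deg}, \code{score}, \code{r2}, \code{wavelength_mm}
#'   (= 360 / k), \code{speed_mm_s} (= wavelength x frequency).
#' @export
fit_plane_wave <- function(phases, geometry, center_freq = NULL,
                           k_max = NULL, theta_step = 1, k_step = 1,
                           min_electrodes = 8) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (length(phases) != nrow(geometry$coords))
    stop("fit_plane_wave: phases must match electrode count")
  use <- usable_electrodes(geometry)
  use <- use[is.finite(phases[use])]
  if (length(use) < min_electrodes)
    stop("fit_plane_wave: fewer than ", min_electrodes,
         " usable electrodes with finite phase")
  k_max <- k_max %||% spatial_nyquist(geometry)
  z <- matrix(exp(1i * phases[use]), ncol = 1)
  eng <- plane_wave_engine(z, geometry$coords[use, , drop = FALSE],
                           k_max = k_max, theta_step = theta_step,
                           k_step = k_step)
  r2 <- series_r2(matrix(phases[use], ncol = 1),
                  geometry$coords[use, , drop = FALSE],
                  eng$theta, eng$k)
  wl <- ifelse(eng$k > 0, 360 / eng$k, Inf)
  data.frame(direction_deg = eng$theta, k_deg_mm = eng$k,
             phase_offset_deg = wrap_deg(rad2deg(eng$offset)),
             score = eng$score, r2 = r2, wavelength_mm = wl,
             speed_mm_s = if (is.null(center_freq)) NA_real_
                          else wl * center_freq)
}

#' Electrode-shuffle permutation null for one timepoint
#'
#' Refits the plane wave after randomly permuting the electrode-to-location
#' assignment, destroying any spatial phase structure while keeping the
#' phase values. The threshold is the stated percentile of the shuffled
#' R-squared values.
#'
#' @param phases per-electrode phase, radians.
#' @param geometry a \code{grid_geometry}.
#' @param n_iter number of shuffles (default 200; < 20 warns).
#' @param percentile one-sided confidence level (default 99).
#' @param seed optional seed for reproducibility.
#' @inheritParams fit_plane_wave
#' @return list with \code{threshold} (R-squared at the percentile) and
#'   \code{null_r2} (all shuffled values).
#' @export
permutation_null <- function(phases, geometry, n_iter = 200,
                             percentile = 99, seed = NULL, k_max = NULL,
                             theta_step = 1, k_step = 1,
                             min_electrodes = 8) {
  if (n_iter < 20) warning("permutation_null: n_iter < 20 gives an unstable percentile")
  use <- usable_electrodes(geometry)
  use <- use[is.finite(phases[use])]
  if (length(use) < min_electrodes)
    stop("permutation_null: fewer than ", min_electrodes, " usable electrodes")
  k_max <- k_max %||% spatial_nyquist(geometry)
  coords <- geometry$coords[use, , drop = FALSE]
  ph <- phases[use]
  with_seed(seed, {
    # permuting the electrode-to-location map = permuting the phase vector
    perm_mat <- vapply(seq_len(n_iter), function(i) sample(ph),
                       numeric(length(ph)))
    lat <- make_lattice(coords, k_max, theta_step, k_step)
    eng <- plane_wave_engine(exp(1i * perm_mat), coords, lattice = lat)
    null_r2 <- series_r2(perm_mat, coords, eng$theta, eng$k)
    list(threshold = unname(stats::quantile(null_r2, percentile / 100)),
         null_r2 = null_r2)
  })
}

#' Fit plane waves to every timepoint of an analytic band
#'
#' Runs the lattice search at each analysis timepoint and, optionally, a
#' per-timepoint electrode-shuffle null. A timepoint is a valid traveling
#' wave when it passes the amplitude/cycle gating of the band, has k > 0,
#' and its R-squared exceeds the permutation-null percentile.
#'
#' @param band an \code{analytic_band}.
#' @param geometry electrode geometry (default: the band's). When a
#'   subsampled geometry (with \code{selected}) is supplied, fits use only
#'   those electrodes but the band's full-grid validity gating is retained.
#' @param null_iters electrode-shuffle iterations per timepoint (default
#'   200; 0 skips the null, leaving \code{null_threshold} = NA and
#'   \code{is_valid} based on gating alone).
#' @param ci_percent one-sided confidence level for validity (default 99).
#' @param seed seed for the permutation null.
#' @inheritParams fit_plane_wave
#' @return a \code{wave_fit_series} data.frame with one row per timepoint:
#'   \code{t}, \code{direction_deg}, \code{k_deg_mm},
#'   \code{phase_offset_deg}, \code{score}, \code{r2},
#'   \code{wavelength_mm}, \code{speed_mm_s}, \code{null_threshold},
#'   \code{gated}, \code{is_valid}.
#' @export
fit_series <- function(band, geometry = NULL, null_iters = 200,
                       ci_percent = 99, seed = 1, k_max = NULL,
                       theta_step = 1, k_step = 1, min_electrodes = 8) {
  stopifnot(inherits(band, "analytic_band"))
  geometry <- geometry %||% band$geometry
  sel <- geometry$selected %||% seq_len(nrow(geometry$coords))
  pos <- setdiff(seq_along(sel), geometry$bad_channels)
  rows <- match(sel[pos], band$channels)   # parent electrode -> band row
  pos <- pos[!is.na(rows)]
  rows <- rows[!is.na(rows)]
  if (length(pos) < min_electrodes)
    stop("fit_series: fewer than ", min_electrodes, " usable electrodes")
  coords <- geometry$coords[pos, , drop = FALSE]
  phase <- band$phase[rows, , drop = FALSE]
  k_max <- k_max %||% spatial_nyquist(geometry)
  nt <- ncol(phase)
  Z <- exp(1i * phase)
  lat <- make_lattice(coords, k_max, theta_step, k_step)
  eng <- plane_wave_engine(Z, coords, lattice = lat)
  r2 <- series_r2(phase, coords, eng$theta, eng$k)
  thr <- rep(NA_real_, nt)
  if (null_iters > 0) {
    # chunk permutations so several share one BLAS pass over the lattice;
    # ~1800 columns per pass keeps the working set cache-friendly
    chunk <- max(1L, floor(1800 / nt))
    null_r2 <- matrix(NA_real_, null_iters, nt)
    with_seed(seed, {
      it <- 0L
      while (it < null_iters) {
        nc <- min(chunk, null_iters - it)
        perms <- replicate(nc, sample(nrow(phase)), simplify = FALSE)
        Zc <- do.call(cbind, lapply(perms, function(p) Z[p, , drop = FALSE]))
        phc <- do.call(cbind, lapply(perms, function(p) phase[p, , drop = FALSE]))
        eng_n <- plane_wave_engine(Zc, coords, lattice = lat)
        r2c <- series_r2(phc, coords, eng_n$theta, eng_n$k)
        null_r2[it + seq_len(nc), ] <-
          matrix(r2c, nrow = nc, ncol = nt, byrow = TRUE)
        it <- it + nc
      }
    })
    thr <- apply(null_r2, 2, stats::quantile, probs = ci_percent / 100)
  }
  wl <- ifelse(eng$k > 0, 360 / eng$k, Inf)
  out <- data.frame(
    t = band$times, direction_deg = eng$theta, k_deg_mm = eng$k,
    phase_offset_deg = wrap_deg(rad2deg(eng$offset)), score = eng$score,
    r2 = r2, wavelength_mm = wl, speed_mm_s = wl * band$center_freq,
    null_threshold = thr, gated = band$valid_mask,
    is_valid = band$valid_mask & eng$k > 0 &
      (if (null_iters > 0) r2 > thr else TRUE))
  attr(out, "center_freq") <- band$center_freq
  attr(out, "fs_analysis") <- band$fs_analysis
  attr(out, "ci_percent") <- ci_percent
  class(out) <- c("wave_fit_series", "data.frame")
  out
}

#' @export
print.wave_fit_series <- function(x, ...) {
  if (!is.null(x$is_valid))
    cat(sprintf("<wave_fit_series> %.2f Hz, %d timepoints @ %g Hz, %d valid (%.1f%%)\n",
                attr(x, "center_freq"), nrow(x), attr(x, "fs_analysis"),
                sum(x$is_valid), 100 * mean(x$is_valid)))
  NextMethod()
}
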