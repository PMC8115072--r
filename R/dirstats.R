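# Direction distributions of valid traveling-wave timepoints: 10-degree
# binning, 60-degree circular smoothing, mode extraction, modality
# classification (bidirectional if the secondary smoothed peak reaches 25%
# of the primary), and circular uniformity testing.

#' Build a circular direction distribution
#'
#' Bins wave travel directions in 10-degree steps, smooths the histogram
#' with a mass-preserving 60-degree circular window (7 bins, half-weight
#' end bins), extracts smoothed local maxima as modes, and classifies the
#' distribution as bidirectional when the second-highest smoothed peak is
#' at least \code{bimodal_frac} of the highest. A Hodges-Ajne uniformity
#' test is attached for bidirectional distributions, a Rayleigh test for
#' unidirectional ones.
#'
#' @param directions travel directions in degrees (valid fits only).
#' @param bin_deg bin width, degrees (default 10).
#' @param smooth_deg smoothing window support, degrees (default 60).
#' @param bimodal_frac secondary/primary peak ratio defining bidirectionality
#'   (default 0.25).
#' @return a \code{direction_distribution}: list with \code{bin_edges},
#'   \code{bin_centers}, \code{counts}, \code{smoothed}, \code{modes}
#'   (1 or 2 directions, degrees), \code{modality}
#'   ("unidirectional"/"bidirectional"), and \code{test}
#'   (name, statistic, p).
#' @export
build_distribution <- function(directions, bin_deg = 10, smooth_deg = 60,
                               bimodal_frac = 0.25) {
  directions <- directions[is.finite(directions)]
  if (!length(directions)) stop("build_distribution: no directions supplied")
  nb <- round(360 / bin_deg)
  edges <- seq(0, 360, by = bin_deg)
  bins <- findInterval(wrap_deg(directions), edges,
                       rightmost.closed = TRUE)
  counts <- tabulate(bins, nbins = nb)
  smoothed <- circular_smooth(counts, smooth_deg / bin_deg)
  centers <- edges[-length(edges)] + bin_deg / 2
  # circular local maxima as plateaus: maximal runs of equal smoothed value
  # whose neighbors on both sides are lower; a plateau's mode is the
  # circular mean of its bin centers
  plat <- smoothed_plateaus(smoothed, centers)
  modality <- "unidirectional"
  modes <- plat$mode[1]
  if (nrow(plat) > 1) {
    if (plat$height[2] >= bimodal_frac * plat$height[1]) {
      modality <- "bidirectional"
      modes <- plat$mode[1:2]
    }
  }
  rad <- deg2rad(directions)
  test <- if (modality == "bidirectional") {
    ha <- hodges_ajne_test(rad)
    list(name = "hodges_ajne", statistic = ha$m, p = ha$p)
  } else {
    rl <- rayleigh_test(rad)
    list(name = "rayleigh", statistic = rl$z, p = rl$p)
  }
  structure(list(bin_edges = edges, bin_centers = centers, counts = counts,
                 smoothed = smoothed, modes = modes, modality = modality,
                 test = test, n = length(directions)),
            class = "direction_distribution")
}

# Locate circular plateaus of the smoothed histogram that dominate both
# neighbors; returns them ordered by height (descending). A flat histogram
# yields one plateau spanning the whole circle.
smoothed_plateaus <- function(smoothed, centers) {
  nb <- length(smoothed)
  if (length(unique(smoothed)) == 1L) {
    return(data.frame(mode = wrap_deg(rad2deg(circ_mean(deg2rad(centers)))),
                      height = smoothed[1]))
  }
  # split the circle into runs of equal value, merging across the wrap
  r <- rle(smoothed)
  run_id <- rep(seq_along(r$values), r$lengths)
  if (r$values[1] == r$values[length(r$values)])
    run_id[run_id == max(run_id)] <- 1L
  ids <- unique(run_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    bins <- which(run_id == id)
    # circular neighbors of the run (handle wrap-merged runs)
    all_n <- setdiff(unique(c((bins - 2) %% nb + 1, (bins %% nb) + 1)), bins)
    if (all(smoothed[all_n] < smoothed[bins[1]])) {
      data.frame(mode = wrap_deg(rad2deg(circ_mean(deg2rad(centers[bins])))),
                 height = smoothed[bins[1]])
    } else NULL
  }))
  out[order(-out$height), , drop = FALSE]
}

# Mass-preserving circular moving average whose support spans `span_bins`
# bins. An even span uses span + 1 weights with half-weight end bins.
circular_smooth <- function(counts, span_bins) {
  span_bins <- round(span_bins)
  if (span_bins %% 2 == 0) {
    w <- c(0.5, rep(1, span_bins - 1), 0.5) / span_bins
  } else {
    w <- rep(1, span_bins) / span_bins
  }
  nb <- length(counts)
  half <- (length(w) - 1) / 2
  ext <- c(counts[(nb - half + 1):nb], counts, counts[1:half])
  as.numeric(stats::filter(ext, w, sides = 2))[(half + 1):(half + nb)]
}

#' @export
print.direction_distribution <- function(x, ...) {
  cat(sprintf("<direction_distribution> n = %d, %s; mode(s): %s deg\n",
              x$n, x$modality,
              paste(sprintf("%.0f", x$modes), collapse = ", ")))
  cat(sprintf("  %s test: statistic = %.3g, p = %.3g\n",
              x$test$name, x$test$statistic, x$test$p))
  invisible(x)
}

#' Split valid timepoints by proximity to two preferred directions
#'
#' Assigns each valid timepoint to one of two wedges of half-width
#' \code{half_width} degrees around the two modes; timepoints outside both
#' wedges are dropped. The wedges must not overlap (modes at least
#' \code{2 * half_width} degrees apart on the circle).
#'
#' @param fits a \code{wave_fit_series}.
#' @param modes numeric length-2: the two preferred directions, degrees.
#' @param half_width wedge half-width, degrees (default 45).
#' @return list with \code{idx1}, \code{idx2} (row indices of \code{fits}),
#'   and \code{labels} (factor over the union, levels "mode1"/"mode2").
#' @export
angle_split <- function(fits, modes, half_width = 45) {
  stopifnot(length(modes) == 2)
  sep <- abs(wrap_pi(deg2rad(modes[1] - modes[2])))
  if (sep < deg2rad(2 * half_width))
    stop("angle_split: wedges overlap (modes < ", 2 * half_width,
         " degrees apart)")
  d <- fits$direction_deg
  ok <- fits$is_valid & is.finite(d)
  d1 <- abs(wrap_pi(deg2rad(d - modes[1])))
  d2 <- abs(wrap_pi(deg2rad(d - modes[2])))
  idx1 <- which(ok & d1 <= deg2rad(half_width))
  idx2 <- which(ok & d2 <= deg2rad(half_width))
  labels <- factor(rep(c("mode1", "mode2"), c(length(idx1), length(idx2))),
                   levels = c("mode1", "mode2"))
  list(idx1 = idx1, idx2 = idx2, labels = labels, modes = modes)
}
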