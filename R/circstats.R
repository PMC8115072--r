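# Circular statistics primitives. All functions take angles in RADIANS unless
# the name says _deg; user-facing wave directions elsewhere are in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

# Wrap degrees into [0, 360)
wrap_deg <- function(x) x %% 360

#' Circular mean of angles
#'
#' @param x angles in radians.
#' @param na.rm drop missing values first.
#' @return mean direction in radians, in (-pi, pi]; `NA` if the resultant
#'   vanishes or no data remain.
#' @export
circ_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  s <- sum(exp(1i * x))
  if (Mod(s) < .Machine$double.eps * length(x)) return(NA_real_)
  Arg(s)
}

#' Mean resultant length
#'
#' Magnitude of the average unit phasor of a set of angles: 0 for perfectly
#' dispersed angles, 1 when all angles coincide.
#'
#' @param x angles in radians.
#' @param na.rm drop missing values first.
#' @return scalar in \code{[0, 1]}.
#' @export
resultant_length <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  Mod(mean(exp(1i * x)))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis of a uniform circular distribution against a
#' unimodal alternative. The p-value uses the standard large-sample
#' approximation (Zar 1999), which is accurate for n >= 10 and underflow-safe
#' for highly concentrated samples.
#'
#' @param x angles in radians.
#' @return list with \code{r_bar} (mean resultant length), \code{z}
#'   (Rayleigh statistic n * r_bar^2), \code{p}, and \code{n}.
#' @export
rayleigh_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("rayleigh_test: need at least 2 angles")
  r_bar <- resultant_length(x)
  z <- n * r_bar^2
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r_bar = r_bar, z = z, p = min(p, 1), n = n)
}

#' Hodges-Ajne test of circular uniformity
#'
#' Omnibus test based on m, the smallest number of observations contained in
#' any closed half-circle; sensitive to multimodal as well as unimodal
#' departures from uniformity. Exact p-value
#' \eqn{p = (n - 2m) \binom{n}{m} 2^{1-n}} for n <= 50, the standard
#' asymptotic approximation above that.
#'
#' @param x angles in radians.
#' @return list with \code{m}, \code{p}, and \code{n}.
#' @export
hodges_ajne_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("hodges_ajne_test: need at least 4 angles")
  m <- half_circle_min(x)
  if (2 * m >= n) {
    p <- 1                       # maximally balanced sample: no evidence
  } else if (n <= 50L) {
    p <- (n - 2 * m) * choose(n, m) / 2^(n - 1)
  } else {
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    p <- sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
  }
  list(m = m, p = min(max(p, 0), 1), n = n)
}

# Minimum count over all closed half-circles. The count as a function of the
# boundary angle changes only when the boundary crosses a data angle, and
# the minimum over closed halves is attained arbitrarily close to (not at)
# data angles, so evaluating between consecutive sorted angles suffices.
half_circle_min <- function(x) {
  n <- length(x)
  a <- x %% (2 * pi)
  # count changes when the boundary or its antipode crosses a data angle;
  # merge near-duplicate events so midpoints stay clear of data angles
  ev <- sort(unique(c(a, (a + pi) %% (2 * pi))))
  gaps <- c(diff(ev), ev[1] + 2 * pi - ev[length(ev)])
  keep <- gaps > 1e-9
  bounds <- (ev[keep] + gaps[keep] / 2) %% (2 * pi)
  counts <- vapply(bounds, function(b) {
    d <- (a - b) %% (2 * pi)
    sum(d < pi)
  }, numeric(1))
  min(counts, n - counts)
}

#' Circular median
#'
#' Angle (restricted to candidate data angles and their antipodes) minimizing
#' the mean circular distance to the sample.
#'
#' @param x angles in radians.
#' @return median direction in radians.
#' @export
circ_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  cand <- c(x, x + pi)
  dev <- vapply(cand, function(m) mean(pi - abs(pi - abs(x - m) %% (2 * pi))), numeric(1))
  wrap_pi(cand[which.min(dev)])
}

#' Fisher common-median test for several circular samples
#'
#' Nonparametric multi-sample test of whether k circular distributions share
#' a common median direction (Fisher 1993, sec. 5.3.2). Counts observations
#' on either side of the pooled circular median and forms a chi-square
#' statistic with k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors of angles in radians (>= 2 groups,
#'   each with n >= 10).
#' @return list with \code{statistic}, \code{df}, \code{p}, \code{n},
#'   and \code{median} (pooled, radians).
#' @export
common_median_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("common_median_test: need a list of >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 10L)) stop("common_median_test: each group needs n >= 10")
  all_ang <- unlist(groups)
  N <- length(all_ang)
  med <- circ_median(all_ang)
  # count per group on the negative side of the pooled median
  m_i <- vapply(groups, function(g) {
    d <- wrap_pi(g - med)
    sum(d < 0)
  }, numeric(1))
  M <- sum(m_i)
  if (M == 0 || M == N) {
    # all observations on one side: no evidence of differing medians
    return(list(statistic = 0, df = length(groups) - 1L, p = 1,
                n = ns, median = med))
  }
  stat <- N^2 / (M * (N - M)) * sum(m_i^2 / ns) - N * M / (N - M)
  stat <- max(stat, 0)
  df <- length(groups) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, n = ns, median = med)
}

#' Circular-circular correlation
#'
#' Jammalamadaka-SenGupta correlation coefficient between two samples of
#' angles; equals 1 when one sample is the other plus a constant rotation.
#'
#' @param a,b angle vectors in radians, equal length.
#' @return correlation in \code{[-1, 1]}; 0 when either sample is degenerate
#'   (all angles identical).
#' @export
circ_corr <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) return(0)
  sa <- sin(a - circ_mean(a))
  sb <- sin(b - circ_mean(b))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < .Machine$double.eps) return(0)
  sum(sa * sb) / den
}

#' Draw angles from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; used by the synthetic-data module
#' and by the statistical calibration tests.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return n angles in radians in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa == 0) return(wrap_pi(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(mu + out)
}
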