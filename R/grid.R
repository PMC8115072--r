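# Electrode grid geometry: the spatial frame for every plane-wave fit.

#' Construct a regular electrode grid
#'
#' Lays electrodes on a regular 2D lattice. Electrode 1 sits at the origin;
#' x increases along columns (posterior to anterior by convention), y along
#' rows (superior to inferior). Electrodes are numbered row-major: electrode
#' \code{(r, c)} has index \code{(r - 1) * n_cols + c}.
#'
#' @param n_rows,n_cols lattice dimensions (default 4 x 8, the microgrid
#'   layout the package targets).
#' @param pitch center-to-center electrode spacing in mm (default 2).
#' @param bad integer indices of channels to exclude from all analyses.
#' @return a \code{grid_geometry} object: list with \code{coords}
#'   (n_electrodes x 2 matrix, mm), \code{pitch}, \code{n_rows},
#'   \code{n_cols}, \code{bad_channels}.
#' @examples
#' g <- make_grid()            # 4 x 8 at 2 mm
#' nrow(g$coords)              # 32
#' @export
make_grid <- function(n_rows = 4, n_cols = 8, pitch = 2, bad = integer(0)) {
  if (n_rows < 1 || n_cols < 1) stop("make_grid: dimensions must be >= 1")
  if (pitch <= 0) stop("make_grid: pitch must be > 0")
  n <- n_rows * n_cols
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) && (min(bad) < 1 || max(bad) > n))
    stop("make_grid: bad-channel indices outside 1..", n)
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  coords <- cbind(x = (cols - 1) * pitch, y = (rows - 1) * pitch)
  structure(list(coords = coords, pitch = pitch,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 bad_channels = bad),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d electrodes at %g mm pitch (%d usable)\n",
              x$n_rows, x$n_cols, x$pitch, length(usable_electrodes(x))))
  invisible(x)
}

#' Indices of usable (non-bad) electrodes
#'
#' @param geometry a \code{grid_geometry}.
#' @return integer vector of electrode indices.
#' @export
usable_electrodes <- function(geometry) {
  setdiff(seq_len(nrow(geometry$coords)), geometry$bad_channels)
}

#' Maximum resolvable spatial frequency of a grid
#'
#' The spatial Nyquist limit: half a cycle (180 degrees of phase) per
#' electrode spacing, i.e. \code{180 / pitch} degrees/mm. A 2 mm pitch gives
#' the 90 degrees/mm ceiling used by the plane-wave grid search.
#'
#' @param geometry a \code{grid_geometry}.
#' @return spatial frequency ceiling in degrees/mm.
#' @export
spatial_nyquist <- function(geometry) 180 / geometry$pitch

#' Rotate electrode coordinates
#'
#' Rigid counterclockwise rotation of all electrode coordinates about their
#' centroid. Used for rotation-equivariance checks: rotating the grid by
#' \code{alpha} rotates fitted wave directions by \code{-alpha}.
#'
#' @param geometry a \code{grid_geometry}.
#' @param alpha_deg rotation angle, degrees counterclockwise.
#' @return a new \code{grid_geometry} with rotated coordinates.
#' @export
rotate_geometry <- function(geometry, alpha_deg) {
  a <- deg2rad(alpha_deg)
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- colMeans(geometry$coords)
  xy <- sweep(geometry$coords, 2, ctr) %*% Rm
  out <- geometry
  out$coords <- sweep(xy, 2, ctr, "+")
  colnames(out$coords) <- c("x", "y")
  out
}

#' Subsample electrodes from a grid
#'
#' Selects a rectangular sub-block (optionally offset along x) or an oblique
#' set of electrodes, returning a geometry restricted to those electrodes.
#' Mirrors control analyses that refit waves on reduced layouts (e.g. 4 x 4
#' blocks stepped anteriorly in one-pitch increments, or 3 x 2 oblique
#' sub-grids) while keeping the timepoints selected on the full grid.
#'
#' @param geometry a \code{grid_geometry}.
#' @param rows,cols dimensions of the sub-block.
#' @param x_offset_mm shift of the block along x in mm (must be a multiple
#'   of the pitch).
#' @param y_offset_mm shift along y in mm (multiple of the pitch).
#' @param electrodes alternatively, explicit electrode indices (overrides
#'   the block selection); used for oblique layouts.
#' @return a \code{grid_geometry} whose \code{coords} contain only the
#'   selected electrodes, with \code{selected} giving their indices in the
#'   parent grid.
#' @export
subsample_electrodes <- function(geometry, rows = NULL, cols = NULL,
                                 x_offset_mm = 0, y_offset_mm = 0,
                                 electrodes = NULL) {
  if (is.null(electrodes)) {
    if (is.null(rows) || is.null(cols))
      stop("subsample_electrodes: give rows/cols or explicit electrodes")
    c0 <- round(x_offset_mm / geometry$pitch)
    r0 <- round(y_offset_mm / geometry$pitch)
    if (r0 + rows > geometry$n_rows || c0 + cols > geometry$n_cols ||
        r0 < 0 || c0 < 0)
      stop("subsample_electrodes: requested block outside the grid")
    rr <- r0 + seq_len(rows)
    cc <- c0 + seq_len(cols)
    electrodes <- as.vector(outer(cc, (rr - 1) * geometry$n_cols, "+"))
  }
  electrodes <- sort(unique(as.integer(electrodes)))
  if (length(electrodes) < 6)
    stop("subsample_electrodes: < 6 electrodes selected")
  if (min(electrodes) < 1 || max(electrodes) > nrow(geometry$coords))
    stop("subsample_electrodes: electrode indices outside the grid")
  out <- geometry
  out$coords <- geometry$coords[electrodes, , drop = FALSE]
  out$bad_channels <- match(intersect(geometry$bad_channels, electrodes),
                            electrodes)
  out$n_rows <- NA_integer_
  out$n_cols <- NA_integer_
  out$selected <- electrodes
  out
}
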