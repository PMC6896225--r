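#' Rotation increment for n-fold symmetry averaging
#'
#' The angular step between symmetry-related images, 360/n degrees
#' (approximately 25.7 degrees for the 14-fold ring).
#'
#' @param order rotational order (>= 1).
#' @return increment in degrees.
#' @export
symmetryIncrement <- function(order) {
  if (order < 1) rwStop("rw_spec_error", "order must be >= 1")
  360 / order
}

#' Synthesise a density map from a trajectory (volmap-style)
#'
#' Every selected bead deposits a normalised isotropic 3-D Gaussian (unit
#' integral, truncated at 4 sigma) on the lattice; per-frame grids are
#' averaged over the requested frames. The grid covers the trajectory
#' box at the requested sampling density (1 Angstrom by default).
#'
#' @param traj a [BeadTrajectory-class].
#' @param selection integer bead rows or a kind name (e.g. `"lipid"`,
#'   `"lipid_head"`).
#' @param spacing voxel spacing, Angstrom.
#' @param sigma Gaussian width per bead, Angstrom.
#' @param frames frame indices to use (default all).
#' @return a [DensityGrid-class].
#' @export
trajectoryToDensity <- function(traj, selection, spacing = 1, sigma = 1,
                                frames = NULL) {
  if (sigma <= 0) rwStop("rw_spec_error", "sigma must be positive")
  if (is.character(selection)) selection <- selectBeads(traj,
                                                        kind = selection)
  if (!length(selection))
    rwStop("rw_selection_error", "selection must be non-empty")
  if (is.null(frames)) frames <- seq_along(traj@times)
  boxA <- apply(traj@boxes[frames, , drop = FALSE], 2, max) * 10
  dims <- as.integer(ceiling(boxA / spacing))
  origin <- rep(spacing / 2, 3)
  axes <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing)
  norm1d <- 1 / sqrt(2 * pi * sigma^2)
  vals <- array(0, dim = dims)
  halo <- 4 * sigma
  for (f in frames) {
    xyzA <- traj@coords[selection, , f, drop = TRUE] * 10
    dim(xyzA) <- c(length(selection), 3)
    for (b in seq_len(nrow(xyzA))) {
      rng <- lapply(1:3, function(a) {
        which(abs(axes[[a]] - xyzA[b, a]) <= halo)
      })
      if (!all(lengths(rng) > 0)) next
      g <- lapply(1:3, function(a)
        norm1d * exp(-(axes[[a]][rng[[a]]] - xyzA[b, a])^2 / (2 * sigma^2)))
      vals[rng[[1]], rng[[2]], rng[[3]]] <-
        vals[rng[[1]], rng[[2]], rng[[3]]] + g[[1]] %o% g[[2]] %o% g[[3]]
    }
  }
  DensityGrid(vals / length(frames), spacing = spacing, origin = origin)
}

# Internal: trilinear sampling of a grid at arbitrary points (N x 3, in
# the grid's Angstrom frame). Points outside the grid extent contribute 0.
trilinearSample <- function(grid, pts) {
  d <- dim(grid@values)
  u <- sweep(sweep(pts, 2, grid@origin), 2, grid@spacing, "/")
  i0 <- floor(u)
  fr <- u - i0
  val <- numeric(nrow(pts))
  v <- grid@values
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ii <- i0[, 1] + a; jj <- i0[, 2] + b; kk <- i0[, 3] + cc
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    w <- (if (a) fr[, 1] else 1 - fr[, 1]) *
         (if (b) fr[, 2] else 1 - fr[, 2]) *
         (if (cc) fr[, 3] else 1 - fr[, 3])
    idx <- 1 + ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok])
    val[ok] <- val[ok] + w[ok] * v[idx]
  }
  val
}

# Internal: voxel-centre coordinates of a lattice as an N x 3 matrix.
latticePoints <- function(origin, spacing, dims) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  cbind(rep(xs, times = dims[2] * dims[3]),
        rep(rep(ys, each = dims[1]), times = dims[3]),
        rep(zs, each = dims[1] * dims[2]))
}

#' Resample a density grid onto another lattice
#'
#' Trilinear interpolation; target points outside the source extent are
#' set to zero. Resampling onto the grid's own lattice is the identity.
#'
#' @param grid source [DensityGrid-class].
#' @param target a [DensityGrid-class] (used as lattice template) or a
#'   list with `origin`, `spacing`, `dims`.
#' @return a [DensityGrid-class] on the target lattice.
#' @export
resampleGrid <- function(grid, target) {
  to <- if (is(target, "DensityGrid") || is(target, "DensityMask"))
    list(origin = target@origin, spacing = target@spacing,
         dims = dim(target@values))
  else target
  to$dims <- as.integer(to$dims)
  if (length(to$spacing) == 1) to$spacing <- rep(to$spacing, 3)
  srcLo <- grid@origin
  srcHi <- grid@origin + (dim(grid@values) - 1) * grid@spacing
  tgtLo <- to$origin
  tgtHi <- to$origin + (to$dims - 1) * to$spacing
  if (any(tgtHi < srcLo) || any(tgtLo > srcHi))
    rwStop("rw_geometry_error", "target lattice is disjoint from the grid")
  pts <- latticePoints(to$origin, to$spacing, to$dims)
  vals <- array(trilinearSample(grid, pts), dim = to$dims)
  DensityGrid(vals, spacing = to$spacing, origin = to$origin)
}

#' n-fold rotational symmetry averaging of a density map
#'
#' Replaces the map by the mean of its `order` rotations about the axis
#' (in 360/order-degree increments), each rotation resampled
#' trilinearly by inverse mapping with zero fill outside the grid.
#' Order 1 is the identity.
#'
#' @param grid a [DensityGrid-class].
#' @param order rotational order (>= 1).
#' @param axisPoint point on the axis, Angstrom; defaults to the lattice
#'   centre.
#' @param axisDir axis direction, default +z.
#' @return a [DensityGrid-class].
#' @export
symmetryAverage <- function(grid, order, axisPoint = NULL,
                            axisDir = c(0, 0, 1)) {
  if (order < 1) rwStop("rw_spec_error", "order must be >= 1")
  d <- dim(grid@values)
  if (is.null(axisPoint))
    axisPoint <- grid@origin + (d - 1) / 2 * grid@spacing
  if (order == 1) return(grid)
  pts <- latticePoints(grid@origin, grid@spacing, d)
  acc <- as.numeric(grid@values)
  inc <- symmetryIncrement(order)
  for (k in seq_len(order - 1)) {
    src <- rotateAboutAxis(pts, axisPoint, axisDir, -k * inc)
    acc <- acc + trilinearSample(grid, src)
  }
  DensityGrid(array(acc / order, dim = d), spacing = grid@spacing,
              origin = grid@origin)
}

#' Estimate the n-fold symmetry axis of a map
#'
#' Grid search over small axis tilts about x and y (the axis passes
#' through the density centre of mass); the score of a candidate axis is
#' the mean Pearson correlation between the map and its order-1 rotated
#' copies about that axis. Returns the argmax.
#'
#' @param grid a [DensityGrid-class] with nonzero variance.
#' @param order rotational order (>= 2).
#' @param tiltSearch half-width of the tilt search, degrees.
#' @param step tilt step, degrees.
#' @return list with `axisPoint`, `axisDir`, `tilt` (degrees about x and
#'   y) and `score`.
#' @export
estimateSymmetryAxis <- function(grid, order, tiltSearch = 2, step = 0.5) {
  if (order < 2) rwStop("rw_spec_error", "order must be >= 2")
  v <- as.numeric(grid@values)
  if (stats::sd(v) == 0)
    rwStop("rw_degenerate_error", "flat map: symmetry axis undefined")
  d <- dim(grid@values)
  pts <- latticePoints(grid@origin, grid@spacing, d)
  w <- pmax(v, 0)
  com <- colSums(pts * w) / sum(w)
  tilts <- seq(-tiltSearch, tiltSearch, by = step)
  inc <- symmetryIncrement(order)
  best <- NULL
  for (tx in tilts) for (ty in tilts) {
    dir <- c(rotationMatrixAxis(c(0, 1, 0), ty) %*%
               rotationMatrixAxis(c(1, 0, 0), tx) %*% c(0, 0, 1))
    score <- mean(vapply(seq_len(order - 1), function(k) {
      src <- rotateAboutAxis(pts, com, dir, -k * inc)
      stats::cor(v, trilinearSample(grid, src))
    }, numeric(1)))
    if (is.null(best) || score > best$score)
      best <- list(axisPoint = com, axisDir = dir, tilt = c(tx, ty),
                   score = score)
  }
  best
}

#' Threshold a map into a boolean mask
#'
#' Selects voxels with density strictly above `level` (the convention
#' used when masking the c-ring interior at level 0.8 in simulated maps).
#'
#' @param grid a [DensityGrid-class].
#' @param level threshold (finite).
#' @return a [DensityMask-class] on the same lattice; the number of
#'   selected voxels is available as `sum(gridValues(mask))`.
#' @export
buildMask <- function(grid, level) {
  if (!is.finite(level)) rwStop("rw_spec_error", "level must be finite")
  new("DensityMask", origin = grid@origin, spacing = grid@spacing,
      values = grid@values > level)
}

#' Masked real-space correlation coefficient between two maps
#'
#' Pearson correlation of the two maps over the masked voxels. If the
#' second map lives on a different lattice it is first resampled onto
#' the first map's lattice; the mask must share the first map's lattice.
#' Being a Pearson correlation, the RSCC is invariant under positive
#' affine rescaling of either map, which is why no absolute density
#' calibration between simulated and experimental maps is needed.
#'
#' @param gridA,gridB [DensityGrid-class] maps.
#' @param mask a [DensityMask-class] on `gridA`'s lattice, or NULL for
#'   all voxels.
#' @return correlation in `[-1, 1]`.
#' @export
rscc <- function(gridA, gridB, mask = NULL) {
  sameLattice <- function(a, b)
    all(dim(a@values) == dim(b@values)) &&
      max(abs(a@origin - b@origin)) < 1e-6 &&
      max(abs(a@spacing - b@spacing)) < 1e-6
  if (!sameLattice(gridA, gridB)) gridB <- resampleGrid(gridB, gridA)
  if (is.null(mask)) {
    sel <- rep(TRUE, length(gridA@values))
  } else {
    if (!sameLattice(gridA, mask))
      rwStop("rw_mask_error", "mask lattice does not match the first map")
    sel <- as.logical(mask@values)
  }
  if (sum(sel) < 2)
    rwStop("rw_mask_error", "mask must select at least 2 voxels")
  av <- as.numeric(gridA@values)[sel]
  bv <- as.numeric(gridB@values)[sel]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    rwStop("rw_degenerate_error", "zero variance over the mask")
  stats::cor(av, bv)
}
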