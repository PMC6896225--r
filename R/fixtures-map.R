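#' Build an exactly Cn-symmetric Gaussian density map
#'
#' Evaluates, analytically at every voxel centre, the sum of each blob
#' replicated at all `order` rotations about the z axis through
#' `axisPoint`. Because every replica is evaluated analytically (no
#' interpolation), the result is Cn-symmetric up to floating-point
#' rounding, which makes it the fixed-point fixture for testing numerical
#' symmetry averaging.
#'
#' @param order rotational order (>= 1).
#' @param blobs list of blobs, each a list with `center` (numeric(3),
#'   Angstrom), `sigma` (Angstrom, > 0) and `amplitude` (peak value).
#'   An empty list gives an all-zero grid.
#' @param dims grid dimensions (3 integers).
#' @param spacing voxel spacing, Angstrom (scalar or numeric(3)).
#' @param origin centre of voxel `[1,1,1]`, Angstrom.
#' @param axisPoint point on the symmetry axis; defaults to the lattice
#'   centre.
#' @return a [DensityGrid-class].
#' @export
makeSymmetricMap <- function(order, blobs, dims = c(48, 48, 48),
                             spacing = 1, origin = c(0, 0, 0),
                             axisPoint = NULL) {
  if (order < 1) rwStop("rw_spec_error", "order must be >= 1")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  dims <- as.integer(dims)
  if (is.null(axisPoint))
    axisPoint <- origin + (dims - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  vals <- array(0, dim = dims)
  for (b in blobs) {
    if (is.null(b$sigma) || b$sigma <= 0)
      rwStop("rw_spec_error", "blob sigma must be positive")
    amp <- if (is.null(b$amplitude)) 1 else b$amplitude
    for (k in seq_len(order) - 1L) {
      th <- 2 * pi * k / order
      cxy <- b$center[1:2] - axisPoint[1:2]
      ck <- c(axisPoint[1] + cxy[1] * cos(th) - cxy[2] * sin(th),
              axisPoint[2] + cxy[1] * sin(th) + cxy[2] * cos(th),
              b$center[3])
      gx <- exp(-(xs - ck[1])^2 / (2 * b$sigma^2))
      gy <- exp(-(ys - ck[2])^2 / (2 * b$sigma^2))
      gz <- exp(-(zs - ck[3])^2 / (2 * b$sigma^2))
      vals <- vals + amp * (gx %o% gy %o% gz)
    }
  }
  DensityGrid(vals, spacing = spacing, origin = origin)
}
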