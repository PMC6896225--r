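#' Construct a BeadSystem
#'
#' @param coords numeric matrix (n x 3), nm.
#' @param kind character vector of bead kinds.
#' @param box numeric(3) box lengths, nm.
#' @param beadId integer ids; defaults to 1..n.
#' @param protomer integer protomer indices (0-based) or NA.
#' @param molecule integer molecule indices (0-based); defaults to one
#'   molecule per bead.
#' @param leaflet leaflet tags (`loop_side`, `nc_side`, `none`).
#' @param periodicXY logical, default TRUE.
#' @return a [BeadSystem-class].
#' @export
BeadSystem <- function(coords, kind, box,
                       beadId = seq_len(nrow(coords)),
                       protomer = rep(NA_integer_, nrow(coords)),
                       molecule = seq_len(nrow(coords)) - 1L,
                       leaflet = rep("none", nrow(coords)),
                       periodicXY = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  obj <- new("BeadSystem",
    beadId = as.integer(beadId), kind = as.character(kind),
    protomer = as.integer(protomer), molecule = as.integer(molecule),
    leaflet = as.character(leaflet), coords = coords,
    box = as.numeric(box), periodicXY = isTRUE(periodicXY))
  validObject(obj)
  obj
}

#' Construct a BeadTrajectory
#'
#' @param system a [BeadSystem-class] bead table.
#' @param times numeric frame times, ps, strictly increasing.
#' @param coords nBeads x 3 x nFrames array (nm), or a list of nBeads x 3
#'   matrices.
#' @param boxes nFrames x 3 matrix of box lengths; defaults to the system
#'   box repeated.
#' @return a [BeadTrajectory-class].
#' @export
BeadTrajectory <- function(system, times, coords, boxes = NULL) {
  if (is.list(coords)) {
    if (length(unique(vapply(coords, nrow, 1L))) > 1)
      rwStop("rw_format_error", "varying bead count across frames")
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3,
                                            length(coords)))
  }
  if (is.null(boxes))
    boxes <- matrix(system@box, nrow = length(times), ncol = 3, byrow = TRUE)
  if (length(times) > 1 && any(diff(times) <= 0))
    rwStop("rw_order_error", "frame times must be strictly increasing")
  obj <- new("BeadTrajectory", system = system, times = as.numeric(times),
             coords = coords, boxes = boxes)
  validObject(obj)
  obj
}

#' Construct a DensityGrid
#'
#' @param values 3-D numeric array, x index fastest.
#' @param spacing per-axis voxel spacing, Angstrom (scalar recycled).
#' @param origin centre of voxel `[1,1,1]`, Angstrom.
#' @return a [DensityGrid-class].
#' @export
DensityGrid <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  obj <- new("DensityGrid", origin = as.numeric(origin),
             spacing = as.numeric(spacing), values = values)
  validObject(obj)
  obj
}

#' Construct a RingSpec
#'
#' Defaults describe the 14-protomer toy ring: two 3-bead columns per
#' protomer on concentric circles, in a 24 x 18 x 12 nm box (the box used
#' for the corresponding coarse-grained assembly systems). The radii are
#' toy placeholders chosen to give a ring-sized pore, not measurements of
#' the real spinach ring.
#'
#' @param nProtomers number of protomers (>= 3), default 14.
#' @param outerRadius,innerRadius column-circle radii, nm.
#' @param beadsPerColumn beads per vertical column.
#' @param columnZSpan vertical extent of each column, nm.
#' @param box box lengths, nm.
#' @return a [RingSpec-class].
#' @export
ringSpec <- function(nProtomers = 14L, outerRadius = 2.6, innerRadius = 1.7,
                     beadsPerColumn = 3L, columnZSpan = 3.2,
                     box = c(24, 18, 12)) {
  obj <- tryCatch(
    new("RingSpec", nProtomers = as.integer(nProtomers),
        outerRadius = outerRadius, innerRadius = innerRadius,
        beadsPerColumn = as.integer(beadsPerColumn),
        columnZSpan = columnZSpan, box = as.numeric(box)),
    error = function(e) rwStop("rw_spec_error", conditionMessage(e)))
  obj
}

#' Construct a PlugSpec
#'
#' @param nLoop,nNC plug lipid counts on the loop-side / NC-side leaflets.
#' @param bulkDensity bulk lipid density per leaflet outside the ring
#'   footprint, per nm2; default 1.5 (the area density of a POPC leaflet).
#' @return a [PlugSpec-class].
#' @export
plugSpec <- function(nLoop = 7L, nNC = 10L, bulkDensity = 1.5) {
  obj <- tryCatch(
    new("PlugSpec", nLoop = as.integer(nLoop), nNC = as.integer(nNC),
        bulkDensity = bulkDensity),
    error = function(e) rwStop("rw_spec_error", conditionMessage(e)))
  obj
}

#' Construct SimParams
#'
#' Defaults define the toy Brownian model: temperature matching the
#' atomistic reference runs, a friction that puts weak-stage relaxation
#' times in the tens of picoseconds, and purely repulsive (WCA) bead
#' contacts. See the methods vignette for the reasoning behind each value.
#'
#' @param temperature Kelvin, default 303.
#' @param gamma per-bead friction, kJ ps mol^-1 nm^-2, default 500.
#' @param dt timestep, ps, default 0.04.
#' @param beadRadii named bead radii, nm.
#' @param epsilon WCA strength, kJ/mol, default 2.5.
#' @param leafletK leaflet-confinement spring constant on lipid heads,
#'   kJ/(mol nm^2), default 5.
#' @param leafletZ named target head z offsets from the midplane, nm.
#' @param cutoff neighbour cutoff, nm, default 0.6.
#' @return a [SimParams-class].
#' @export
simParams <- function(temperature = 303, gamma = 500, dt = 0.04,
                      beadRadii = c(protomer_bead = 0.25, lipid_head = 0.23,
                                    lipid_tail = 0.23, water = 0.15,
                                    site = 0),
                      epsilon = 2.5, leafletK = 5,
                      leafletZ = c(loop_side = 1.4, nc_side = -1.4),
                      cutoff = 0.6) {
  obj <- tryCatch(
    new("SimParams", temperature = temperature, gamma = gamma, dt = dt,
        beadRadii = beadRadii, epsilon = epsilon, leafletK = leafletK,
        leafletZ = leafletZ, cutoff = cutoff),
    error = function(e) rwStop("rw_spec_error", conditionMessage(e)))
  obj
}

#' Construct a BiasProtocol
#'
#' The default strong schedule is three consecutive 200 ps stages at 10,
#' 100 and 1000 kJ/(mol nm^2). The default weak-stage spring constant is
#' the toy-scaled analog of the mid-range scan value (see the methods
#' vignette for the scaling argument).
#'
#' @param weakK weak-stage spring constant, kJ/(mol nm^2) per bead.
#' @param weakMaxDuration maximum weak-stage duration, ps.
#' @param checkInterval RMSD sampling interval, ps.
#' @param convergenceThreshold weak-stage convergence threshold, Angstrom.
#' @param strongStages matrix with columns k, duration.
#' @param assembledThreshold assembled-outcome threshold, Angstrom;
#'   default 5, covering the 3.0-4.7 Angstrom band typical of converged
#'   weak-stage assemblies.
#' @return a [BiasProtocol-class].
#' @export
biasProtocol <- function(weakK = 10, weakMaxDuration = 300,
                         checkInterval = 1, convergenceThreshold = 5,
                         strongStages = cbind(k = c(10, 100, 1000),
                                              duration = c(200, 200, 200)),
                         assembledThreshold = 5) {
  obj <- tryCatch(
    new("BiasProtocol", weakK = weakK, weakMaxDuration = weakMaxDuration,
        checkInterval = checkInterval,
        convergenceThreshold = convergenceThreshold,
        strongStages = strongStages,
        assembledThreshold = assembledThreshold),
    error = function(e) rwStop("rw_spec_error", conditionMessage(e)))
  obj
}

#' Select bead indices by kind and other labels
#'
#' @param x a [BeadSystem-class] or [BeadTrajectory-class].
#' @param kind bead kinds to keep, or NULL for all.
#' @param molecule molecule indices to keep, or NULL.
#' @param leaflet leaflet tags to keep, or NULL.
#' @return integer vector of bead row indices.
#' @export
selectBeads <- function(x, kind = NULL, molecule = NULL, leaflet = NULL) {
  s <- if (is(x, "BeadTrajectory")) x@system else x
  keep <- rep(TRUE, length(s@beadId))
  if (!is.null(kind)) {
    if (identical(kind, "lipid")) kind <- c("lipid_head", "lipid_tail")
    keep <- keep & s@kind %in% kind
  }
  if (!is.null(molecule)) keep <- keep & s@molecule %in% molecule
  if (!is.null(leaflet)) keep <- keep & s@leaflet %in% leaflet
  which(keep)
}
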