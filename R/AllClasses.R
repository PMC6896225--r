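BEAD_KINDS <- c("protomer_bead", "lipid_head", "lipid_tail", "water", "site")
LEAFLET_TAGS <- c("loop_side", "nc_side", "none")

#' BeadSystem: a bead-level configuration of the ring/membrane system
#'
#' Holds one configuration of a coarse bead model: stable integer bead ids,
#' a bead kind per bead (protomer bead, lipid head, lipid tail, water or
#' analysis site), protomer / molecule / leaflet labels, coordinates in nm
#' and an orthorhombic box. The membrane plane is x,y (periodic); the
#' membrane normal and ring symmetry axis is +z (non-periodic).
#'
#' @slot beadId integer, unique and stable across derived trajectories.
#' @slot kind character, one of `protomer_bead`, `lipid_head`,
#'   `lipid_tail`, `water`, `site`.
#' @slot protomer integer protomer index (0-based) or NA for non-protomer
#'   beads.
#' @slot molecule integer molecule index (0-based); every bead belongs to a
#'   molecule.
#' @slot leaflet character, `loop_side`, `nc_side` or `none`. By package
#'   convention the loop side is +z.
#' @slot coords numeric matrix (n x 3), nm.
#' @slot box numeric(3) box lengths, nm.
#' @slot periodicXY logical, minimum-image convention in x,y.
#' @exportClass BeadSystem
setClass("BeadSystem",
  representation(
    beadId = "integer",
    kind = "character",
    protomer = "integer",
    molecule = "integer",
    leaflet = "character",
    coords = "matrix",
    box = "numeric",
    periodicXY = "logical"
  )
)

setValidity("BeadSystem", function(object) {
  n <- length(object@beadId)
  msgs <- character(0)
  if (anyDuplicated(object@beadId)) msgs <- c(msgs, "bead ids must be unique")
  if (length(object@kind) != n || length(object@protomer) != n ||
      length(object@molecule) != n || length(object@leaflet) != n ||
      nrow(object@coords) != n || ncol(object@coords) != 3)
    msgs <- c(msgs, "per-bead slots must all have one entry per bead")
  if (!all(object@kind %in% BEAD_KINDS))
    msgs <- c(msgs, "unknown bead kind")
  if (!all(object@leaflet %in% LEAFLET_TAGS))
    msgs <- c(msgs, "unknown leaflet tag")
  if (length(object@box) != 3 || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    msgs <- c(msgs, "box lengths must be three positive numbers")
  prot <- object@kind == "protomer_bead"
  if (any(prot & is.na(object@protomer)))
    msgs <- c(msgs, "protomer beads must carry a protomer index")
  if (any(object@kind == "water" & !is.na(object@protomer)))
    msgs <- c(msgs, "water beads must not carry a protomer index")
  # each lipid molecule has exactly one head bead
  lip <- object@kind %in% c("lipid_head", "lipid_tail")
  if (any(lip)) {
    nHead <- tapply(object@kind[lip] == "lipid_head", object@molecule[lip], sum)
    if (any(nHead != 1L))
      msgs <- c(msgs, "every lipid molecule must have exactly one head bead")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' BeadTrajectory: time-ordered frames over a fixed bead table
#'
#' @slot system the [BeadSystem-class] bead table (coordinates are those of
#'   the first frame's parent configuration; per-frame coordinates live in
#'   `coords`).
#' @slot times numeric, strictly increasing frame times in ps.
#' @slot coords 3-D numeric array (nBeads x 3 x nFrames), nm.
#' @slot boxes numeric matrix (nFrames x 3), per-frame box lengths in nm.
#' @exportClass BeadTrajectory
setClass("BeadTrajectory",
  representation(
    system = "BeadSystem",
    times = "numeric",
    coords = "array",
    boxes = "matrix"
  )
)

setValidity("BeadTrajectory", function(object) {
  msgs <- character(0)
  nf <- length(object@times)
  if (nf > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "frame times must be strictly increasing")
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msgs <- c(msgs, "coords must be an nBeads x 3 x nFrames array")
  else {
    if (d[1] != length(object@system@beadId))
      msgs <- c(msgs, "frame coordinate count must equal bead count")
    if (d[3] != nf)
      msgs <- c(msgs, "one coordinate slab per frame required")
  }
  if (nrow(object@boxes) != nf || ncol(object@boxes) != 3)
    msgs <- c(msgs, "one box per frame required")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' RigidTransform: proper rigid-body motion (rotation + translation)
#'
#' @slot rotation 3x3 orthonormal matrix with det = +1.
#' @slot translation numeric(3), nm.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) >= 1e-10)
    return("rotation must be orthonormal (||R'R - I|| < 1e-10)")
  if (abs(det(R) - 1) >= 1e-10) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3) return("translation must be length 3")
  TRUE
})

#' DensityGrid: scalar field on a regular 3-D lattice
#'
#' Voxel `[i, j, k]` is centred at `origin + (c(i,j,k) - 1) * spacing`.
#' The first array index (x) varies fastest in memory, the MRC/CCP4
#' convention. All lattice quantities are in Angstrom; values are in
#' arbitrary density units.
#'
#' @slot origin numeric(3), centre of the first voxel, Angstrom.
#' @slot spacing numeric(3), per-axis voxel spacing, Angstrom.
#' @slot values 3-D numeric array.
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(origin = "numeric", spacing = "numeric", values = "array")
)

setValidity("DensityGrid", function(object) {
  if (length(object@origin) != 3 || length(object@spacing) != 3)
    return("origin and spacing must be length 3")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (length(dim(object@values)) != 3) return("values must be a 3-D array")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' DensityMask: boolean companion lattice of a DensityGrid
#'
#' @slot origin,spacing as in [DensityGrid-class]; must match the parent
#'   grid exactly.
#' @slot values 3-D logical array.
#' @exportClass DensityMask
setClass("DensityMask",
  representation(origin = "numeric", spacing = "numeric", values = "array")
)

setValidity("DensityMask", function(object) {
  if (length(dim(object@values)) != 3 || !is.logical(object@values))
    return("mask values must be a 3-D logical array")
  if (length(object@origin) != 3 || length(object@spacing) != 3)
    return("origin and spacing must be length 3")
  TRUE
})

#' RingSpec: geometry of a synthetic reference ring
#'
#' Each protomer is modelled as two rigid vertical bead columns (standing
#' for its two transmembrane helices) placed on concentric circles.
#'
#' @slot nProtomers integer >= 3; 14 for the spinach chloroplast c-ring.
#' @slot outerRadius,innerRadius circle radii of the outer/inner bead
#'   columns, nm.
#' @slot beadsPerColumn integer, beads per vertical column.
#' @slot columnZSpan vertical extent of each column, nm.
#' @slot box numeric(3), box lengths, nm.
#' @exportClass RingSpec
setClass("RingSpec",
  representation(
    nProtomers = "integer", outerRadius = "numeric", innerRadius = "numeric",
    beadsPerColumn = "integer", columnZSpan = "numeric", box = "numeric"
  )
)

setValidity("RingSpec", function(object) {
  if (object@nProtomers < 3L) return("nProtomers must be >= 3")
  if (object@innerRadius >= object@outerRadius)
    return("innerRadius must be smaller than outerRadius")
  if (object@innerRadius <= 0) return("radii must be positive")
  if (object@beadsPerColumn < 1L) return("beadsPerColumn must be >= 1")
  if (object@columnZSpan <= 0) return("columnZSpan must be positive")
  if (length(object@box) != 3 || any(object@box <= 0))
    return("box must be three positive lengths")
  TRUE
})

#' PlugSpec: lipids placed inside the ring, per leaflet
#'
#' @slot nLoop,nNC number of plug lipids on the loop-side (+z) and NC-side
#'   (-z) leaflets.
#' @slot bulkDensity bulk lipid density outside the ring footprint, per nm2
#'   per leaflet.
#' @exportClass PlugSpec
setClass("PlugSpec",
  representation(nLoop = "integer", nNC = "integer", bulkDensity = "numeric")
)

setValidity("PlugSpec", function(object) {
  if (object@nLoop < 0L || object@nNC < 0L)
    return("plug lipid counts must be >= 0")
  if (object@bulkDensity < 0) return("bulkDensity must be >= 0")
  TRUE
})

#' SimParams: Brownian-dynamics parameters for the toy assembly model
#'
#' @slot temperature Kelvin.
#' @slot gamma friction coefficient, kJ ps mol^-1 nm^-2 (per bead).
#' @slot dt timestep, ps.
#' @slot beadRadii named numeric, bead radius per kind, nm; WCA repulsion
#'   between two beads vanishes beyond the sum of their radii.
#' @slot epsilon WCA repulsion strength, kJ/mol.
#' @slot leafletK harmonic leaflet-confinement constant acting on lipid
#'   head beads, kJ/(mol nm^2).
#' @slot leafletZ named numeric, target head z offset from the bilayer
#'   midplane per leaflet, nm (`loop_side` positive by convention).
#' @slot cutoff neighbour-search cutoff, nm; must be >= the largest pair
#'   contact distance.
#' @exportClass SimParams
setClass("SimParams",
  representation(
    temperature = "numeric", gamma = "numeric", dt = "numeric",
    beadRadii = "numeric", epsilon = "numeric",
    leafletK = "numeric", leafletZ = "numeric", cutoff = "numeric"
  )
)

setValidity("SimParams", function(object) {
  for (s in c("temperature", "gamma", "dt", "epsilon", "leafletK", "cutoff"))
    if (length(slot(object, s)) != 1 || slot(object, s) < 0 ||
        !is.finite(slot(object, s)))
      return(sprintf("%s must be a single non-negative finite number", s))
  if (object@dt <= 0 || object@gamma <= 0)
    return("dt and gamma must be positive")
  if (!all(BEAD_KINDS %in% names(object@beadRadii)))
    return("beadRadii must name every bead kind")
  if (!all(c("loop_side", "nc_side") %in% names(object@leafletZ)))
    return("leafletZ must name loop_side and nc_side")
  TRUE
})

#' BiasProtocol: staged harmonic restraint schedule
#'
#' A weak pulling stage runs until the lab-frame protomer RMSD to the
#' reference drops below `convergenceThreshold` (or `weakMaxDuration`
#' expires, in which case the run is classified not assembled). Converged
#' runs are refined by the ordered strong stages, by default 10, 100 and
#' 1000 kJ/(mol nm^2) for 200 ps each.
#'
#' @slot weakK weak-stage spring constant, kJ/(mol nm^2) per bead.
#' @slot weakMaxDuration maximum weak-stage duration, ps.
#' @slot checkInterval RMSD sampling interval, ps.
#' @slot convergenceThreshold weak-stage convergence threshold, Angstrom.
#' @slot strongStages numeric matrix with columns `k` (kJ/(mol nm^2),
#'   strictly increasing) and `duration` (ps).
#' @slot assembledThreshold final-RMSD threshold for the assembled outcome,
#'   Angstrom.
#' @exportClass BiasProtocol
setClass("BiasProtocol",
  representation(
    weakK = "numeric", weakMaxDuration = "numeric", checkInterval = "numeric",
    convergenceThreshold = "numeric", strongStages = "matrix",
    assembledThreshold = "numeric"
  )
)

setValidity("BiasProtocol", function(object) {
  if (object@weakK < 0) return("weakK must be >= 0")
  if (object@weakMaxDuration <= 0 || object@checkInterval <= 0)
    return("durations must be positive")
  ss <- object@strongStages
  if (nrow(ss) > 0) {
    if (!all(c("k", "duration") %in% colnames(ss)))
      return("strongStages needs columns k and duration")
    if (any(diff(ss[, "k"]) <= 0) && nrow(ss) > 1)
      return("strong-stage spring constants must be strictly increasing")
    if (any(ss[, "duration"] <= 0))
      return("strong-stage durations must be positive")
  }
  if (object@convergenceThreshold <= 0 || object@assembledThreshold <= 0)
    return("thresholds must be positive")
  TRUE
})

#' AssemblyResult: classified outcome of one assembly run
#'
#' @slot outcome `"assembled"` or `"not_assembled"`.
#' @slot convergenceTime first sampled time (ps) at which the weak-stage
#'   RMSD dropped strictly below the convergence threshold, or NA.
#' @slot finalRmsd final lab-frame protomer RMSD to the reference, Angstrom.
#' @slot rmsdTrace data.frame with columns time (ps), rmsd (Angstrom),
#'   stage.
#' @slot nLoop,nNC,nTotal encapsulated-lipid counts on the final frame.
#' @slot trajectory the concatenated [BeadTrajectory-class] of all stages.
#' @exportClass AssemblyResult
setClass("AssemblyResult",
  representation(
    outcome = "character", convergenceTime = "numeric", finalRmsd = "numeric",
    rmsdTrace = "data.frame", nLoop = "integer", nNC = "integer",
    nTotal = "integer", trajectory = "BeadTrajectory"
  )
)

setValidity("AssemblyResult", function(object) {
  if (!object@outcome %in% c("assembled", "not_assembled"))
    return("outcome must be assembled or not_assembled")
  if (object@nTotal != object@nLoop + object@nNC)
    return("nTotal must equal nLoop + nNC")
  TRUE
})

#' RingRegion: the half-ring inner volume used for residence analysis
#'
#' The membrane-plane polygon of outer-column protomer centroids, ordered by
#' azimuth, together with the bilayer midplane and vertical half-extent.
#'
#' @slot polygon numeric matrix (nProtomers x 2), nm.
#' @slot zMid bilayer midplane, nm.
#' @slot zExtent vertical half-extent of the region, nm.
#' @exportClass RingRegion
setClass("RingRegion",
  representation(polygon = "matrix", zMid = "numeric", zExtent = "numeric")
)

setValidity("RingRegion", function(object) {
  if (nrow(object@polygon) < 3) return("polygon needs >= 3 vertices")
  if (ncol(object@polygon) != 2) return("polygon must be n x 2")
  if (object@zExtent <= 0) return("zExtent must be positive")
  TRUE
})
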