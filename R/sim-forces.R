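# Internal: translate a BeadSystem + SimParams into the flat vectors the
# compiled core consumes. Analysis sites are inert (negative radius
# sentinel) and static; protomers are rigid bodies with frozen z; lipids
# are rigid bodies free in z; waters are free beads.
simArgs <- function(system, params, reference = NULL) {
  kind <- system@kind
  radii <- unname(params@beadRadii[kind])
  radii[kind == "site"] <- -1
  zMid <- system@box[3] / 2
  leafletTarget <- rep(NA_real_, length(kind))
  isHead <- kind == "lipid_head"
  leafletTarget[isHead] <- zMid + params@leafletZ[system@leaflet[isHead]]
  # dense body ids: protomers first, then lipid molecules
  bodyId <- rep(-1L, length(kind))
  isProt <- kind == "protomer_bead"
  protLevels <- sort(unique(system@protomer[isProt]))
  bodyId[isProt] <- match(system@protomer[isProt], protLevels) - 1L
  nProtBodies <- length(protLevels)
  isLip <- kind %in% c("lipid_head", "lipid_tail")
  lipLevels <- sort(unique(system@molecule[isLip]))
  bodyId[isLip] <- nProtBodies + match(system@molecule[isLip], lipLevels) - 1L
  bodyAllowZ <- c(rep(FALSE, nProtBodies), rep(TRUE, length(lipLevels)))
  isStatic <- kind == "site"

  biasRows <- integer(0)
  refCoords <- matrix(0, 0, 3)
  if (!is.null(reference)) {
    biasRows <- which(isProt)
    hit <- match(system@beadId[biasRows], reference@beadId)
    if (anyNA(hit))
      rwStop("rw_topology_error",
             "reference must share bead ids with the protomer beads")
    refCoords <- reference@coords[hit, , drop = FALSE]
  }
  list(radii = radii, leafletTarget = leafletTarget, bodyId = bodyId,
       bodyAllowZ = bodyAllowZ, isStatic = isStatic,
       biasRows = biasRows - 1L, refCoords = refCoords)
}

#' Forces on every bead of the toy assembly model
#'
#' Sum of (a) WCA repulsion between beads of different molecules within
#' the pair cutoff, (b) harmonic leaflet confinement on lipid head beads
#' and (c) the harmonic positional bias pulling protomer beads toward the
#' reference. Forces are analytic gradients of [computePotential()];
#' Newton's third law holds exactly for the pair part.
#'
#' @param system a [BeadSystem-class].
#' @param reference reference [BeadSystem-class] sharing protomer bead
#'   ids, or NULL for no bias.
#' @param kBias bias spring constant, kJ/(mol nm^2) per bead.
#' @param params a [SimParams-class].
#' @return numeric matrix (n x 3) of forces, kJ mol^-1 nm^-1.
#' @export
computeForces <- function(system, reference = NULL, kBias = 0,
                          params = simParams()) {
  a <- simArgs(system, params, reference)
  .cppForces(system@coords, a$radii, params@epsilon, system@box, a$bodyId,
             a$leafletTarget, params@leafletK, a$refCoords, a$biasRows,
             kBias, params@cutoff)
}

#' Total potential energy of the toy assembly model
#'
#' @inheritParams computeForces
#' @return potential energy, kJ/mol.
#' @export
computePotential <- function(system, reference = NULL, kBias = 0,
                             params = simParams()) {
  a <- simArgs(system, params, reference)
  .cppPotential(system@coords, a$radii, params@epsilon, system@box,
                a$bodyId, a$leafletTarget, params@leafletK, a$refCoords,
                a$biasRows, kBias, params@cutoff)
}

#' One overdamped (Brownian) update from externally supplied forces
#'
#' Reference implementation of the integrator update rule, useful for
#' testing against analytic limits: each free bead moves by
#' `F/gamma * dt + sqrt(2 kBT dt / gamma) * xi`; beads of a rigid body
#' move together, with the net force and torque mapped to an in-plane
#' translation plus a rotation about the body's vertical axis (protomer z
#' frozen, lipid z free). The production path ([runStage()]) applies the
#' identical rule in compiled code.
#'
#' @param system a [BeadSystem-class].
#' @param forces numeric matrix (n x 3), kJ mol^-1 nm^-1.
#' @param params a [SimParams-class].
#' @return the updated [BeadSystem-class].
#' @export
stepBrownian <- function(system, forces, params = simParams()) {
  a <- simArgs(system, params)
  kBT <- kBOLTZ * params@temperature
  dt <- params@dt
  gamma <- params@gamma
  x <- system@coords
  box <- system@box
  nBodies <- max(a$bodyId) + 1L
  for (b in seq_len(max(nBodies, 0L)) - 1L) {
    rows <- which(a$bodyId == b)
    if (!length(rows)) next
    nb <- length(rows)
    ctr <- colMeans(x[rows, 1:2, drop = FALSE])
    Fnet <- colSums(forces[rows, , drop = FALSE])
    rx <- x[rows, 1] - ctr[1]; ry <- x[rows, 2] - ctr[2]
    tau <- sum(rx * forces[rows, 2] - ry * forces[rows, 1])
    gtr <- gamma * nb
    ntr <- sqrt(2 * kBT * dt / gtr)
    d <- c(Fnet[1] / gtr * dt + ntr * rnorm(1),
           Fnet[2] / gtr * dt + ntr * rnorm(1),
           if (a$bodyAllowZ[b + 1L]) Fnet[3] / gtr * dt + ntr * rnorm(1)
           else 0)
    Ig <- gamma * sum(rx^2 + ry^2)
    dth <- if (Ig > 1e-12)
      tau / Ig * dt + sqrt(2 * kBT * dt / Ig) * rnorm(1) else 0
    c1 <- cos(dth); s1 <- sin(dth)
    x[rows, 1] <- ctr[1] + c1 * rx - s1 * ry + d[1]
    x[rows, 2] <- ctr[2] + s1 * rx + c1 * ry + d[2]
    x[rows, 3] <- x[rows, 3] + d[3]
    wrap <- box[1:2] * floor((ctr + d[1:2]) / box[1:2])
    x[rows, 1] <- x[rows, 1] - wrap[1]
    x[rows, 2] <- x[rows, 2] - wrap[2]
  }
  free <- which(a$bodyId < 0 & !a$isStatic)
  nf <- sqrt(2 * kBT * dt / gamma)
  for (i in free) {
    d <- forces[i, ] / gamma * dt + nf * rnorm(3)
    x[i, 1] <- (x[i, 1] + d[1]) %% box[1]
    x[i, 2] <- (x[i, 2] + d[2]) %% box[2]
    x[i, 3] <- x[i, 3] + d[3]
  }
  if (any(!is.finite(x)))
    rwStop("rw_divergence_error", "divergence at step 1: non-finite coordinates")
  system@coords <- x
  system
}
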