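# Toy lipid geometry: a vertical 3-bead rod. Head at the leaflet target
# height, two tail beads stacked toward the bilayer midplane. These offsets
# match the simParams() leaflet defaults.
LIPID_HEAD_Z <- 1.4
LIPID_TAIL_DZ <- c(0.5, 1.0)

#' Evaluate an expression with a temporary RNG seed
#' @noRd
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = .GlobalEnv)
  old <- if (hadSeed) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

#' Build an exactly Cn-symmetric reference ring
#'
#' Each protomer consists of two rigid vertical bead columns (a stand-in
#' for its two transmembrane helices) on concentric circles about the ring
#' axis, which is +z through the box centre. Rotating the output by 360/n
#' degrees and permuting protomer indices reproduces the coordinates to
#' machine precision.
#'
#' @param spec a [RingSpec-class].
#' @return a [BeadSystem-class] of protomer beads only.
#' @export
makeReferenceRing <- function(spec = ringSpec()) {
  if (!is(spec, "RingSpec")) rwStop("rw_spec_error", "spec must be a RingSpec")
  n <- spec@nProtomers
  ctr <- spec@box / 2
  zs <- seq(-spec@columnZSpan / 2, spec@columnZSpan / 2,
            length.out = spec@beadsPerColumn) + ctr[3]
  bpc <- spec@beadsPerColumn
  coords <- matrix(0, nrow = n * 2 * bpc, ncol = 3)
  protomer <- integer(n * 2 * bpc)
  row <- 1L
  for (p in seq_len(n) - 1L) {
    phi <- 2 * pi * p / n
    for (r in c(spec@outerRadius, spec@innerRadius)) {
      for (z in zs) {
        coords[row, ] <- c(ctr[1] + r * cos(phi), ctr[2] + r * sin(phi), z)
        protomer[row] <- p
        row <- row + 1L
      }
    }
  }
  BeadSystem(coords = coords, kind = rep("protomer_bead", nrow(coords)),
             box = spec@box, protomer = protomer, molecule = protomer)
}

#' Hexagonal lattice points over a rectangle
#' @noRd
hexLattice <- function(a, lx, ly, offset = c(0, 0)) {
  # commensurate spacings so that wrapped boundary gaps equal the lattice
  # spacing (no accidental close contacts across the periodic seam)
  nx <- max(1L, round(lx / a))
  ax <- lx / nx
  dy <- a * sqrt(3) / 2
  ny <- max(1L, round(ly / dy))
  dyy <- ly / ny
  pts <- NULL
  for (i in seq_len(ny) - 1L) {
    xo <- if (i %% 2 == 1) ax / 2 else 0
    xs <- (seq_len(nx) - 1L) * ax + xo
    pts <- rbind(pts, cbind(xs, i * dyy))
  }
  pts <- sweep(pts, 2, -offset)
  pts[, 1] <- pts[, 1] %% lx
  pts[, 2] <- pts[, 2] %% ly
  pts
}

#' Assemble the bead rows of one 3-bead lipid rod
#' @noRd
lipidBeads <- function(xy, leaflet, zMid) {
  sgn <- if (leaflet == "loop_side") 1 else -1
  zHead <- zMid + sgn * LIPID_HEAD_Z
  cbind(rep(xy[1], 3), rep(xy[2], 3),
        c(zHead, zHead - sgn * LIPID_TAIL_DZ[1],
          zHead - sgn * LIPID_TAIL_DZ[2]))
}

#' Build the split assembly system and its intact reference
#'
#' The ring of `spec` is split into two half-rings displaced by
#' `+/- separation/2` along x (the side of each protomer chosen by the sign
#' of the cosine of its ring azimuth). Plug lipids from `plug` are placed
#' on a hexagonal grid inside the central pore region, and a bulk lipid
#' bath at `plug@bulkDensity` per leaflet fills the remaining membrane
#' area, gap between the half-rings included. Protomer beads share ids
#' with the returned reference, so at separation 0 the system coincides
#' with the reference for protomer beads.
#'
#' @param spec a [RingSpec-class].
#' @param plug a [PlugSpec-class].
#' @param separation centre-to-centre half-ring displacement, nm.
#' @param seed RNG seed for the bulk-lattice jitter.
#' @param jitter maximal in-plane jitter of bulk lipids, nm.
#' @return list with elements `system` and `reference`
#'   ([BeadSystem-class]).
#' @export
makeAssemblySystem <- function(spec = ringSpec(), plug = plugSpec(),
                               separation = 5, seed = 1, jitter = 0.08) {
  if (separation < 0) rwStop("rw_spec_error", "separation must be >= 0")
  ref <- makeReferenceRing(spec)
  ctr <- spec@box / 2
  if (separation / 2 + spec@outerRadius + 0.5 > spec@box[1] / 2)
    rwStop("rw_spec_error", "box too small for the requested separation")
  n <- spec@nProtomers
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  side <- ifelse(cos(phi) >= 0, 1, -1)
  sysCoords <- ref@coords
  shift <- side[ref@protomer + 1L] * separation / 2
  sysCoords[, 1] <- sysCoords[, 1] + shift

  # plug lipids: hexagonal grid inside the pore, ordered by radius
  a <- 0.7
  hp <- hexLattice(a, 4 * spec@innerRadius, 4 * spec@innerRadius)
  hp <- sweep(hp, 2, c(2 * spec@innerRadius, 2 * spec@innerRadius))
  hp <- sweep(hp, 2, -ctr[1:2])
  r2 <- (hp[, 1] - ctr[1])^2 + (hp[, 2] - ctr[2])^2
  hp <- hp[order(r2), , drop = FALSE]
  inPore <- sqrt((hp[, 1] - ctr[1])^2 + (hp[, 2] - ctr[2])^2) <=
    spec@innerRadius - 0.35
  hp <- hp[inPore, , drop = FALSE]
  if (nrow(hp) < max(plug@nLoop, plug@nNC))
    rwStop("rw_spec_error", "pore too small for the requested plug lipids")

  # bulk lipids: jittered hexagonal bath outside the protein footprint and
  # outside the plug disc
  dens <- plug@bulkDensity
  lipXY <- list(loop_side = hp[seq_len(plug@nLoop), , drop = FALSE],
                nc_side = hp[seq_len(plug@nNC), , drop = FALSE])
  if (dens > 0) {
    ab <- sqrt(2 / (sqrt(3) * dens))
    colXY <- unique(round(sysCoords[, 1:2], 9))
    withSeed(seed, {
      for (lf in c("loop_side", "nc_side")) {
        off <- if (lf == "loop_side") c(0, 0) else c(ab / 2, ab * sqrt(3) / 4)
        pts <- hexLattice(ab, spec@box[1], spec@box[2], offset = off)
        pts <- pts + matrix(runif(length(pts), -jitter, jitter),
                            ncol = 2)
        pts[, 1] <- pts[, 1] %% spec@box[1]
        pts[, 2] <- pts[, 2] %% spec@box[2]
        keep <- rep(TRUE, nrow(pts))
        for (ci in seq_len(nrow(colXY))) {
          d2 <- (pts[, 1] - colXY[ci, 1])^2 + (pts[, 2] - colXY[ci, 2])^2
          keep <- keep & d2 > 0.75^2
        }
        keep <- keep & ((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 >
                          (spec@innerRadius + 0.3)^2)
        lipXY[[lf]] <- rbind(lipXY[[lf]], pts[keep, , drop = FALSE])
      }
    })
  }

  nProtBeads <- nrow(sysCoords)
  coordsList <- list(sysCoords)
  kind <- rep("protomer_bead", nProtBeads)
  protomer <- ref@protomer
  molecule <- ref@molecule
  leaflet <- rep("none", nProtBeads)
  mol <- max(ref@molecule) + 1L
  for (lf in c("loop_side", "nc_side")) {
    xy <- lipXY[[lf]]
    for (i in seq_len(nrow(xy))) {
      coordsList[[length(coordsList) + 1L]] <-
        lipidBeads(xy[i, ], lf, ctr[3])
      kind <- c(kind, c("lipid_head", "lipid_tail", "lipid_tail"))
      protomer <- c(protomer, rep(NA_integer_, 3))
      molecule <- c(molecule, rep(mol, 3))
      leaflet <- c(leaflet, rep(lf, 3))
      mol <- mol + 1L
    }
  }
  allCoords <- do.call(rbind, coordsList)
  sys <- BeadSystem(coords = allCoords, kind = kind, box = spec@box,
                    protomer = protomer, molecule = molecule,
                    leaflet = leaflet)
  # overlap invariant: head beads must not touch
  heads <- sys@coords[sys@kind == "lipid_head" & sys@leaflet == "loop_side",
                      , drop = FALSE]
  for (h in list(heads,
                 sys@coords[sys@kind == "lipid_head" &
                              sys@leaflet == "nc_side", , drop = FALSE])) {
    if (nrow(h) > 1) {
      dm <- as.matrix(stats::dist(h[, 1:2]))
      diag(dm) <- Inf
      if (min(dm) <= 0.46)
        rwStop("rw_spec_error", "lipid placement produced overlapping heads")
    }
  }
  list(system = sys, reference = ref)
}
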