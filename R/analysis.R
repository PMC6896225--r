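#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' Vectorised crossing-number implementation; points lying on a polygon
#' edge (to 1e-9 nm) are classified inside.
#'
#' @param pts numeric matrix (n x 2).
#' @param poly numeric matrix (m x 2) of polygon vertices in order.
#' @return logical vector.
#' @export
pointInPolygon <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  onEdge <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    ex <- xj - xi; ey <- yj - yi
    len <- sqrt(ex^2 + ey^2)
    if (len > 0) {
      dperp <- abs(ex * (pts[, 2] - yi) - ey * (pts[, 1] - xi)) / len
      tpar <- ((pts[, 1] - xi) * ex + (pts[, 2] - yi) * ey) / len^2
      onEdge <- onEdge | (dperp < 1e-9 & tpar >= -1e-12 & tpar <= 1 + 1e-12)
    }
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2]))
    xq <- xi + (xj - xi) * (pts[, 2] - yi) / (yj - yi)
    crosses <- crosses & pts[, 1] < xq
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' The ring inner region of one configuration
#'
#' The inner volume is bounded laterally by the polygon of outer-column
#' protomer centroids (ordered by azimuth about their common centroid,
#' so for two separated half-rings the polygon spans both halves and the
#' gap) and vertically by `zExtent` either side of the mean protomer z.
#' Within each protomer, the outer column is the half of its beads
#' farther from the overall protomer centroid.
#'
#' @param system a [BeadSystem-class] with >= 3 protomers.
#' @param zExtent vertical half-extent, nm (default 2, the bilayer span).
#' @return a [RingRegion-class].
#' @export
ringRegion <- function(system, zExtent = 2) {
  isProt <- system@kind == "protomer_bead"
  prot <- system@protomer[isProt]
  ids <- sort(unique(prot))
  if (length(ids) < 3)
    rwStop("rw_geometry_error", "need >= 3 protomers to define the region")
  xy <- system@coords[isProt, 1:2, drop = FALSE]
  z <- system@coords[isProt, 3]
  gctr <- colMeans(xy)
  verts <- t(vapply(ids, function(p) {
    rows <- which(prot == p)
    d <- sqrt((xy[rows, 1] - gctr[1])^2 + (xy[rows, 2] - gctr[2])^2)
    outer <- rows[d >= stats::median(d)]
    # columns are vertical: keep the farther half (outer column beads)
    colMeans(xy[outer, , drop = FALSE])
  }, numeric(2)))
  vctr <- colMeans(verts)
  ord <- order(atan2(verts[, 2] - vctr[2], verts[, 1] - vctr[1]))
  new("RingRegion", polygon = verts[ord, , drop = FALSE],
      zMid = mean(z), zExtent = zExtent)
}

#' Classify lipids as inside/outside the ring region, with leaflet
#'
#' A lipid is inside when its head bead (x,y) falls inside the region
#' polygon (even-odd rule, boundary inside) and its head z lies within
#' the region's vertical extent. The leaflet is assigned per frame from
#' the sign of the head height above the midplane (positive = loop side).
#'
#' @param system a [BeadSystem-class].
#' @param region a [RingRegion-class].
#' @return data.frame with columns molecule, inside, leaflet.
#' @export
classifyLipids <- function(system, region) {
  isHead <- system@kind == "lipid_head"
  lipMols <- unique(system@molecule[system@kind %in%
                                      c("lipid_head", "lipid_tail")])
  if (!all(lipMols %in% system@molecule[isHead]))
    rwStop("rw_topology_error", "lipid molecule without a head bead")
  mol <- system@molecule[isHead]
  xyz <- system@coords[isHead, , drop = FALSE]
  inPoly <- pointInPolygon(xyz[, 1:2, drop = FALSE], region@polygon)
  inZ <- abs(xyz[, 3] - region@zMid) <= region@zExtent
  data.frame(
    molecule = mol,
    inside = inPoly & inZ,
    leaflet = ifelse(xyz[, 3] - region@zMid > 0, "loop_side", "nc_side")
  )
}

# Internal: per-frame classification over a trajectory. The region is
# recomputed from each frame's protomer positions.
classifyFrames <- function(traj, zExtent = 2) {
  nf <- length(traj@times)
  lapply(seq_len(nf), function(f) {
    s <- getFrame(traj, f)
    classifyLipids(s, ringRegion(s, zExtent = zExtent))
  })
}

#' Count encapsulated lipids per frame and leaflet
#'
#' @param traj a [BeadTrajectory-class].
#' @param zExtent region vertical half-extent, nm.
#' @return list with `perFrame` (data.frame frame, time, nLoop, nNC,
#'   nTotal), `timeAveraged` and `final` (named numeric).
#' @export
countEncapsulated <- function(traj, zExtent = 2) {
  cls <- classifyFrames(traj, zExtent)
  perFrame <- do.call(rbind, lapply(seq_along(cls), function(f) {
    cc <- cls[[f]]
    nl <- sum(cc$inside & cc$leaflet == "loop_side")
    nn <- sum(cc$inside & cc$leaflet == "nc_side")
    data.frame(frame = f, time = traj@times[f], nLoop = nl, nNC = nn,
               nTotal = nl + nn)
  }))
  list(
    perFrame = perFrame,
    timeAveraged = c(nLoop = mean(perFrame$nLoop),
                     nNC = mean(perFrame$nNC),
                     nTotal = mean(perFrame$nTotal)),
    final = c(nLoop = utils::tail(perFrame$nLoop, 1),
              nNC = utils::tail(perFrame$nNC, 1),
              nTotal = utils::tail(perFrame$nTotal, 1))
  )
}

#' Residence times of lipids in the ring inner volume
#'
#' Maximal runs of consecutive inside frames become residence records.
#' The duration convention is `(t_lastInside + dt) - t_firstInside` with
#' `dt` the local frame spacing (per-gap for irregular sampling).
#' Records touching either trajectory end are flagged censored and are
#' excluded from the summary statistics unless `includeCensored`.
#'
#' @param traj a [BeadTrajectory-class] with >= 2 frames (a single frame
#'   yields only censored records).
#' @param zExtent region vertical half-extent, nm.
#' @param includeCensored include censored records in the summary mean.
#' @return list with `records` (data.frame molecule, entry, exit,
#'   duration, censored) and `summary` (n, meanDuration, maxDuration).
#' @export
residenceTimes <- function(traj, zExtent = 2, includeCensored = FALSE) {
  cls <- classifyFrames(traj, zExtent)
  nf <- length(traj@times)
  times <- traj@times
  gaps <- if (nf > 1) diff(times) else 0
  mols <- if (nf) sort(unique(cls[[1]]$molecule)) else integer(0)
  recs <- list()
  for (m in mols) {
    insideSeq <- vapply(cls, function(cc) cc$inside[cc$molecule == m],
                        logical(1))
    r <- rle(insideSeq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      f1 <- starts[k]; f2 <- ends[k]
      dtLast <- if (f2 < nf) gaps[f2]
                else if (nf > 1) gaps[nf - 1]
                else 0
      recs[[length(recs) + 1L]] <- data.frame(
        molecule = m, entry = times[f1],
        exit = times[f2] + dtLast,
        duration = times[f2] + dtLast - times[f1],
        censored = f1 == 1L || f2 == nf
      )
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(molecule = integer(0), entry = numeric(0),
                             exit = numeric(0), duration = numeric(0),
                             censored = logical(0))
  use <- if (includeCensored) records else
    records[!records$censored, , drop = FALSE]
  list(records = records,
       summary = c(n = nrow(use),
                   meanDuration = if (nrow(use)) mean(use$duration)
                                  else NA_real_,
                   maxDuration = if (nrow(use)) max(use$duration)
                                 else NA_real_))
}

#' Detect lipid extrusion events
#'
#' An extrusion is an inside-to-outside transition that is not reversed
#' within the debounce window (the molecule stays outside for at least
#' `debounce` frames, or until the trajectory ends). The event direction
#' is the molecule's leaflet at its last inside frame.
#'
#' @param traj a [BeadTrajectory-class].
#' @param debounce debounce window, frames.
#' @param zExtent region vertical half-extent, nm.
#' @return data.frame with columns molecule, frame, time, direction
#'   (possibly empty).
#' @export
detectExtrusions <- function(traj, debounce = 10, zExtent = 2) {
  cls <- classifyFrames(traj, zExtent)
  nf <- length(traj@times)
  mols <- if (nf) sort(unique(cls[[1]]$molecule)) else integer(0)
  out <- list()
  for (m in mols) {
    rowsOf <- function(cc) which(cc$molecule == m)
    insideSeq <- vapply(cls, function(cc) cc$inside[rowsOf(cc)], logical(1))
    leafSeq <- vapply(cls, function(cc) cc$leaflet[rowsOf(cc)], character(1))
    for (f in seq_len(nf - 1L)) {
      if (insideSeq[f] && !insideSeq[f + 1L]) {
        horizon <- min(nf, f + debounce)
        if (!any(insideSeq[(f + 1L):horizon])) {
          out[[length(out) + 1L]] <- data.frame(
            molecule = m, frame = f + 1L, time = traj@times[f + 1L],
            direction = leafSeq[f])
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(molecule = integer(0), frame = integer(0),
                  time = numeric(0), direction = character(0))
}

#' Per-frame solvent contacts with site beads
#'
#' For every frame and every site bead, counts the distinct solvent
#' molecules having any selected bead within the cutoff (minimum image in
#' x,y).
#'
#' @param traj a [BeadTrajectory-class].
#' @param sites integer bead rows of the sites (or a kind name, e.g.
#'   `"site"`).
#' @param solvent integer bead rows of the solvent (or a kind name, e.g.
#'   `"water"`).
#' @param cutoffA contact cutoff, Angstrom (default 4).
#' @return data.frame with columns frame, time, site (bead id), count.
#' @export
contactSeries <- function(traj, sites = "site", solvent = "water",
                          cutoffA = 4) {
  s <- traj@system
  if (is.character(sites)) sites <- selectBeads(traj, kind = sites)
  if (is.character(solvent)) solvent <- selectBeads(traj, kind = solvent)
  if (!length(sites) || !length(solvent))
    rwStop("rw_selection_error", "site and solvent selections must be non-empty")
  cut <- cutoffA / 10
  out <- list()
  for (f in seq_along(traj@times)) {
    xyz <- traj@coords[, , f, drop = TRUE]
    dim(xyz) <- c(dim(traj@coords)[1], 3)
    box <- traj@boxes[f, ]
    for (si in sites) {
      d <- sweep(xyz[solvent, , drop = FALSE], 2, xyz[si, ])
      d <- minImageXY(d, box)
      hit <- rowSums(d^2) <= cut^2
      out[[length(out) + 1L]] <- data.frame(
        frame = f, time = traj@times[f], site = s@beadId[si],
        count = length(unique(s@molecule[solvent][hit])))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "cutoffA") <- cutoffA
  res
}

#' Time-averaged z-density profile of a bead selection
#'
#' Normalised so that the profile integrates to one: the sum of densities
#' times the bin width equals 1. Bins are half-open `[low, high)`.
#'
#' @param traj a [BeadTrajectory-class].
#' @param selection integer bead rows or a kind name.
#' @param binWidth bin width, nm.
#' @return data.frame with columns zLow, zHigh, density.
#' @export
zProfile <- function(traj, selection, binWidth = 0.1) {
  if (is.character(selection)) selection <- selectBeads(traj,
                                                        kind = selection)
  if (!length(selection))
    rwStop("rw_selection_error", "selection must be non-empty")
  zAll <- as.numeric(traj@coords[selection, 3, ])
  lz <- max(traj@boxes[, 3])
  edges <- (0:ceiling(lz / binWidth - 1e-9)) * binWidth
  idx <- pmin(pmax(floor(zAll / binWidth), 0), length(edges) - 2L) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(zLow = edges[-length(edges)], zHigh = edges[-1],
             density = counts / (sum(counts) * binWidth))
}

#' Vertical displacement of the lipid plug relative to the bulk bilayer
#'
#' Per leaflet (assigned per frame from the head height), the mean head z
#' of inside lipids minus the mean head z of outside lipids, averaged
#' over frames where both populations exist. Positive values point
#' toward the loop side (+z).
#'
#' @param traj a [BeadTrajectory-class].
#' @param zExtent region vertical half-extent, nm.
#' @return named numeric: loop_side and nc_side displacement, nm.
#' @export
plugDisplacement <- function(traj, zExtent = 2) {
  cls <- classifyFrames(traj, zExtent)
  s <- traj@system
  isHead <- s@kind == "lipid_head"
  headRows <- which(isHead)
  headMol <- s@molecule[isHead]
  sums <- list(loop_side = numeric(0), nc_side = numeric(0))
  for (f in seq_along(traj@times)) {
    cc <- cls[[f]]
    z <- traj@coords[headRows, 3, f]
    for (lf in c("loop_side", "nc_side")) {
      sel <- cc$leaflet == "loop_side"
      if (lf == "nc_side") sel <- !sel
      mIn <- cc$molecule[cc$inside & sel]
      mOut <- cc$molecule[!cc$inside & sel]
      if (length(mIn) && length(mOut))
        sums[[lf]] <- c(sums[[lf]],
                        mean(z[headMol %in% mIn]) -
                          mean(z[headMol %in% mOut]))
    }
  }
  if (!length(sums$loop_side) && !length(sums$nc_side))
    rwStop("rw_degenerate_error",
           "no frame with both inside and outside lipids")
  c(loop_side = if (length(sums$loop_side)) mean(sums$loop_side)
                else NA_real_,
    nc_side = if (length(sums$nc_side)) mean(sums$nc_side) else NA_real_)
}
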