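#' Build a trajectory realising a scripted ground truth exactly
#'
#' Generates a trajectory around a fixed reference ring in which every
#' lipid's inside/outside status, every water-site contact distance and
#' any systematic head-height shift are dictated by the script, so that
#' downstream analyses (residence times, extrusion events, contact series,
#' plug displacement) have exact expected values.
#'
#' Lipids listed in `lipidScript` sit strictly inside the ring polygon
#' during their scripted frame intervals (on a sunflower arrangement well
#' within the pore) and on a wide circle outside the ring otherwise.
#' Waters sit parked far from all sites except in frames where
#' `waterScript` pins them at an exact distance (placed along +z from the
#' site, so the scripted distance is reproduced to machine precision).
#'
#' @param spec a [RingSpec-class]; the protomer beads are static.
#' @param nFrames number of frames.
#' @param dtPs frame spacing, ps.
#' @param lipidScript data.frame with columns `lipid` (1-based molecule
#'   label), `leaflet`, `start`, `end` (1-based inclusive frame range of
#'   an inside interval); several rows per lipid give several intervals.
#'   Overlapping intervals for one lipid are a script error. NULL for no
#'   lipids.
#' @param waterScript data.frame with columns `water` (1-based label),
#'   `frame`, `site` (row index into `sites`), `distA` (scripted
#'   distance, Angstrom). NULL for no waters.
#' @param nWaters number of water molecules (labels used by
#'   `waterScript` must not exceed it); defaults to the largest label.
#' @param sites matrix (k x 3) of site-bead coordinates, nm; NULL for
#'   none.
#' @param insideZShift head z shift (nm, along +z, i.e. positive toward
#'   the loop side) applied to lipids while inside: displaces the plug
#'   relative to the surrounding bilayer.
#' @param zNoiseSd per-frame Gaussian noise on every lipid head z, nm.
#' @param seed RNG seed for the z noise.
#' @return a [BeadTrajectory-class].
#' @export
makeScriptedTrajectory <- function(spec = ringSpec(), nFrames, dtPs = 1000,
                                   lipidScript = NULL, waterScript = NULL,
                                   nWaters = NULL, sites = NULL,
                                   insideZShift = 0, zNoiseSd = 0,
                                   seed = 1) {
  ref <- makeReferenceRing(spec)
  ctr <- spec@box / 2
  lipIds <- if (is.null(lipidScript) || !nrow(lipidScript)) integer(0)
            else sort(unique(lipidScript$lipid))
  if (!is.null(lipidScript) && nrow(lipidScript)) {
    for (id in lipIds) {
      iv <- lipidScript[lipidScript$lipid == id, , drop = FALSE]
      iv <- iv[!is.na(iv$start) & !is.na(iv$end), , drop = FALSE]
      if (!nrow(iv)) next  # lipid exists but is never inside
      if (any(iv$start > iv$end) || any(iv$start < 1) ||
          any(iv$end > nFrames))
        rwStop("rw_script_error",
               sprintf("invalid interval for lipid %d", id))
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
        rwStop("rw_script_error",
               sprintf("overlapping inside intervals for lipid %d", id))
    }
  }
  nLip <- length(lipIds)
  if (is.null(nWaters))
    nWaters <- if (is.null(waterScript) || !nrow(waterScript)) 0L
               else max(waterScript$water)
  nSites <- if (is.null(sites)) 0L else nrow(sites)

  # static bead-table scaffold
  kind <- ref@kind; protomer <- ref@protomer; molecule <- ref@molecule
  leaflet <- rep("none", length(ref@beadId))
  mol <- max(ref@molecule) + 1L
  lipLeaflet <- setNames(rep("loop_side", nLip), lipIds)
  if (nLip) {
    for (i in seq_len(nLip)) {
      lf <- lipidScript$leaflet[lipidScript$lipid == lipIds[i]][1]
      lipLeaflet[i] <- lf
      kind <- c(kind, c("lipid_head", "lipid_tail", "lipid_tail"))
      protomer <- c(protomer, rep(NA_integer_, 3))
      molecule <- c(molecule, rep(mol, 3)); mol <- mol + 1L
      leaflet <- c(leaflet, rep(lf, 3))
    }
  }
  if (nWaters) {
    kind <- c(kind, rep("water", nWaters))
    protomer <- c(protomer, rep(NA_integer_, nWaters))
    molecule <- c(molecule, seq_len(nWaters) - 1L + mol)
    mol <- mol + nWaters
    leaflet <- c(leaflet, rep("none", nWaters))
  }
  if (nSites) {
    kind <- c(kind, rep("site", nSites))
    protomer <- c(protomer, rep(NA_integer_, nSites))
    molecule <- c(molecule, seq_len(nSites) - 1L + mol)
    leaflet <- c(leaflet, rep("none", nSites))
  }
  nBead <- length(kind)
  nProtBead <- length(ref@beadId)

  # scripted positions
  golden <- pi * (3 - sqrt(5))
  insideXY <- function(i) {
    r <- 0.9 * spec@innerRadius * sqrt(i / max(nLip, 1))
    c(ctr[1] + r * cos(i * golden), ctr[2] + r * sin(i * golden))
  }
  outsideXY <- function(i) {
    r <- spec@outerRadius + 2.0
    th <- 2 * pi * i / max(nLip, 1)
    c(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  }
  parkedXY <- function(w) c(0.5 + 0.4 * ((w - 1) %% 8),
                            0.5 + 0.4 * ((w - 1) %/% 8))

  insideMask <- matrix(FALSE, nrow = nLip, ncol = nFrames)
  if (nLip) {
    for (i in seq_len(nLip)) {
      iv <- lipidScript[lipidScript$lipid == lipIds[i], , drop = FALSE]
      iv <- iv[!is.na(iv$start) & !is.na(iv$end), , drop = FALSE]
      for (r in seq_len(nrow(iv)))
        insideMask[i, iv$start[r]:iv$end[r]] <- TRUE
    }
  }

  arr <- array(0, dim = c(nBead, 3, nFrames))
  noise <- if (zNoiseSd > 0)
    withSeed(seed, matrix(rnorm(nLip * nFrames, 0, zNoiseSd),
                          nrow = max(nLip, 1)))
  else matrix(0, nrow = max(nLip, 1), ncol = nFrames)
  for (f in seq_len(nFrames)) {
    arr[seq_len(nProtBead), , f] <- ref@coords
    if (nLip) {
      for (i in seq_len(nLip)) {
        inside <- insideMask[i, f]
        xy <- if (inside) insideXY(i) else outsideXY(i)
        lf <- lipLeaflet[i]
        shift <- if (inside) insideZShift else 0  # +z = toward loop side
        beads <- lipidBeads(xy, lf, ctr[3])
        beads[, 3] <- beads[, 3] + shift + noise[i, f]
        arr[nProtBead + (i - 1L) * 3L + 1:3, , f] <- beads
      }
    }
    if (nWaters) {
      for (w in seq_len(nWaters)) {
        row <- nProtBead + nLip * 3L + w
        sc <- if (!is.null(waterScript))
          waterScript[waterScript$water == w & waterScript$frame == f, ,
                      drop = FALSE]
        else NULL
        if (!is.null(sc) && nrow(sc) > 1)
          rwStop("rw_script_error",
                 sprintf("conflicting contacts for water %d frame %d", w, f))
        if (!is.null(sc) && nrow(sc) == 1) {
          st <- sites[sc$site, ]
          arr[row, , f] <- c(st[1], st[2], st[3] + sc$distA / 10)
        } else {
          arr[row, , f] <- c(parkedXY(w), ctr[3])
        }
      }
    }
    if (nSites)
      arr[nBead - nSites + seq_len(nSites), , f] <- sites
  }
  sys <- BeadSystem(coords = arr[, , 1, drop = TRUE], kind = kind,
                    box = spec@box, protomer = protomer,
                    molecule = molecule, leaflet = leaflet)
  BeadTrajectory(sys, times = (seq_len(nFrames) - 1) * dtPs, coords = arr)
}
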