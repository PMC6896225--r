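test_that("reference rings are exactly Cn-symmetric for n = 3..17", {
  for (n in c(3, 8, 14, 17)) {
    spec <- ringSpec(nProtomers = n)
    ring <- makeReferenceRing(spec)
    bpc <- 2 * spec@beadsPerColumn
    rot <- rotateAboutAxis(coords(ring), spec@box / 2, c(0, 0, 1), 360 / n)
    # rotating protomer p onto protomer p+1 (cyclic index permutation)
    perm <- c((bpc + 1):(n * bpc), 1:bpc)
    expect_lt(max(abs(rot - coords(ring)[perm, ])), 1e-9)
  }
  ring <- makeReferenceRing(ringSpec())
  expect_equal(colMeans(coords(ring)), c(12, 9, 6), tolerance = 1e-12)
  expect_error(ringSpec(innerRadius = 3, outerRadius = 2.6),
               class = "rw_spec_error")
})

test_that("assembly systems split the ring and fill the bath", {
  asm <- makeAssemblySystem(separation = 5)
  isProt <- beadKind(asm$system) == "protomer_bead"
  # uniform +/- 2.5 nm x displacement of all protomer beads -> 25 A
  expect_equal(rmsd(coords(asm$system)[isProt, ], coords(asm$reference)),
               25, tolerance = 1e-9)
  expect_identical(beadIds(asm$system)[isProt], beadIds(asm$reference))

  asm0 <- makeAssemblySystem(separation = 0)
  isProt0 <- beadKind(asm0$system) == "protomer_bead"
  expect_equal(rmsd(coords(asm0$system)[isProt0, ],
                    coords(asm0$reference)), 0)

  expect_error(makeAssemblySystem(separation = 25),
               class = "rw_spec_error")
})

test_that("bulk lipid count matches the area-density oracle", {
  spec <- ringSpec()
  asm <- makeAssemblySystem(spec, plugSpec(0, 0, bulkDensity = 1.5),
                            separation = 5)
  nLip <- length(unique(moleculeIndex(asm$system)[
    beadKind(asm$system) == "lipid_head"]))
  # independent area estimate: Monte Carlo integration of the free area
  # (box minus protomer-column and pore exclusion zones)
  set.seed(99)
  pts <- cbind(runif(2e4, 0, 24), runif(2e4, 0, 18))
  colXY <- unique(coords(asm$system)[
    beadKind(asm$system) == "protomer_bead", 1:2])
  free <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(colXY)))
    free <- free & (pts[, 1] - colXY[i, 1])^2 +
      (pts[, 2] - colXY[i, 2])^2 > 0.75^2
  free <- free & (pts[, 1] - 12)^2 + (pts[, 2] - 9)^2 > 2^2
  areaFree <- 24 * 18 * mean(free)
  expected <- 2 * areaFree * 1.5  # both leaflets
  expect_lt(abs(nLip - expected) / expected, 0.1)
})

test_that("plug lipids land inside and respect the overlap invariant", {
  asm <- makeAssemblySystem(separation = 0, plug = plugSpec(7, 10))
  s <- asm$system
  heads <- which(beadKind(s) == "lipid_head")
  for (lf in c("loop_side", "nc_side")) {
    h <- coords(s)[heads[leafletTag(s)[heads] == lf], 1:2]
    dm <- as.matrix(dist(h))
    diag(dm) <- Inf
    expect_gt(min(dm), 0.46)  # pairwise head distance > bead diameter
  }
  cnt <- countEncapsulated(staticTrajectory(s))$final
  expect_equal(unname(cnt), c(7, 10, 17))
})

test_that("symmetric map fixtures match direct analytic summation", {
  blob <- list(center = c(12, 17, 12), sigma = 2.5, amplitude = 1.3)
  m <- makeSymmetricMap(14, list(blob), dims = c(24, 24, 24))
  # independent oracle: non-separable direct evaluation per voxel
  ctr <- c(11.5, 11.5, 11.5)
  oracle <- array(0, dim = c(24, 24, 24))
  for (k in 0:13) {
    th <- 2 * pi * k / 14
    cxy <- blob$center[1:2] - ctr[1:2]
    ck <- c(ctr[1] + cxy[1] * cos(th) - cxy[2] * sin(th),
            ctr[2] + cxy[1] * sin(th) + cxy[2] * cos(th), blob$center[3])
    for (i in 1:24) for (j in 1:24) for (l in 1:24) {
      d2 <- sum((c(i, j, l) - 1 - ck)^2)
      oracle[i, j, l] <- oracle[i, j, l] +
        blob$amplitude * exp(-d2 / (2 * blob$sigma^2))
    }
  }
  expect_lt(max(abs(gridValues(m) - oracle)), 1e-12)

  # an on-axis blob is rotation invariant: any order gives the order-1 map
  onax <- list(list(center = c(11.5, 11.5, 14), sigma = 2, amplitude = 1))
  m1 <- makeSymmetricMap(1, onax, dims = c(24, 24, 24))
  m14 <- makeSymmetricMap(14, onax, dims = c(24, 24, 24))
  expect_lt(max(abs(gridValues(m14) - 14 * gridValues(m1))), 1e-12)

  expect_equal(max(abs(gridValues(makeSymmetricMap(3, list())))), 0)
  expect_error(makeSymmetricMap(3, list(list(center = c(0, 0, 0),
                                             sigma = -1))),
               class = "rw_spec_error")
})

test_that("scripted trajectories realise their ground truth exactly", {
  scr <- data.frame(lipid = 1, leaflet = "loop_side", start = 10, end = 19)
  tr <- makeScriptedTrajectory(nFrames = 30, dtPs = 1000,
                               lipidScript = scr)
  rt <- residenceTimes(tr)
  expect_equal(nrow(rt$records), 1)
  expect_equal(rt$records$duration, 10000)  # 10 ns
  expect_false(rt$records$censored)

  # water at 3.9 A of a site counts as a contact in exactly those frames
  sites <- matrix(c(12, 9, 6.5), 1, 3)
  ws <- data.frame(water = 1, frame = 1:5, site = 1, distA = 3.9)
  tw <- makeScriptedTrajectory(nFrames = 8, dtPs = 100, waterScript = ws,
                               sites = sites)
  cs <- contactSeries(tw)
  expect_equal(cs$count, c(rep(1, 5), rep(0, 3)))

  # empty script: protomer beads only, analyses return empty results
  te <- makeScriptedTrajectory(nFrames = 4, dtPs = 100)
  expect_true(all(beadKind(te@system) == "protomer_bead"))
  expect_equal(nrow(residenceTimes(te)$records), 0)
  expect_equal(nrow(detectExtrusions(te)), 0)

  expect_error(makeScriptedTrajectory(
    nFrames = 10, dtPs = 100,
    lipidScript = data.frame(lipid = c(1, 1), leaflet = "loop_side",
                             start = c(2, 4), end = c(5, 8))),
    class = "rw_script_error")
})

test_that("generators are deterministic and survive I/O round trips", {
  a <- makeAssemblySystem(separation = 5, seed = 7)
  b <- makeAssemblySystem(separation = 5, seed = 7)
  expect_identical(coords(a$system), coords(b$system))
  c2 <- makeAssemblySystem(separation = 5, seed = 8)
  expect_false(identical(coords(a$system), coords(c2$system)))

  scr <- data.frame(lipid = 1:3, leaflet = "nc_side", start = c(1, 5, 2),
                    end = c(4, 9, 10))
  tr <- makeScriptedTrajectory(nFrames = 10, dtPs = 500,
                               lipidScript = scr)
  f <- withr::local_tempfile(fileext = ".xyz.gz")
  writeTrajectoryXYZ(tr, f)
  tr2 <- readTrajectoryXYZ(f)
  expect_equal(residenceTimes(tr2)$records, residenceTimes(tr)$records)
})
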