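test_that("deposited kernels are normalised and frame-averaged", {
  sys <- BeadSystem(coords = matrix(c(1.2, 0.9, 0.6), 1, 3),
                    kind = "lipid_head", box = c(2.4, 1.8, 1.2),
                    molecule = 0L, leaflet = "loop_side")
  g <- trajectoryToDensity(staticTrajectory(sys), "lipid_head")
  expect_equal(sum(gridValues(g)) * prod(gridSpacing(g)), 1,
               tolerance = 1e-3)
  g10 <- trajectoryToDensity(staticTrajectory(sys, times = 0:9),
                             "lipid_head")
  expect_lt(max(abs(gridValues(g10) - gridValues(g))), 1e-12)
  expect_error(trajectoryToDensity(staticTrajectory(sys), "water"),
               class = "rw_selection_error")
})

test_that("two-bead densities match the analytic Gaussian sum", {
  xy <- rbind(c(1.0, 0.8, 0.7), c(1.5, 1.1, 0.5))
  sys <- BeadSystem(coords = xy, kind = rep("lipid_head", 2),
                    box = c(2.4, 1.8, 1.2), molecule = 0:1,
                    leaflet = rep("loop_side", 2))
  g <- trajectoryToDensity(staticTrajectory(sys), "lipid_head",
                           spacing = 1, sigma = 1)
  d <- gridDims(g)
  vox <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  ctr <- sweep(sweep(vox - 1, 2, gridSpacing(g), "*"), 2, -gridOrigin(g))
  norm3 <- (2 * pi)^(-1.5)
  analytic <- rep(0, nrow(vox))
  for (b in 1:2) {
    dd <- sweep(ctr, 2, xy[b, ] * 10)
    inCube <- rowSums(abs(dd) <= 4) == 3  # per-axis 4-sigma truncation
    analytic[inCube] <- analytic[inCube] +
      norm3 * exp(-rowSums(dd[inCube, , drop = FALSE]^2) / 2)
  }
  got <- as.numeric(gridValues(g))
  expect_lt(max(abs(got - analytic)), 1e-10)

  # linearity in frames: concatenation = frame-count-weighted average
  sysB <- sys
  coords(sysB) <- xy + 0.2
  trA <- staticTrajectory(sys, 0)
  trB <- staticTrajectory(sysB, 0)
  trAB <- BeadTrajectory(sys, c(0, 10),
                         array(c(coords(sys), coords(sysB)),
                               dim = c(2, 3, 2)))
  gA <- gridValues(trajectoryToDensity(trA, "lipid_head"))
  gB <- gridValues(trajectoryToDensity(trB, "lipid_head"))
  gAB <- gridValues(trajectoryToDensity(trAB, "lipid_head"))
  expect_lt(max(abs(gAB - (gA + gB) / 2)), 1e-12)
})

test_that("trilinear resampling is exact where it should be", {
  m <- makeSymmetricMap(3, list(list(center = c(8, 11, 8), sigma = 2,
                                     amplitude = 1)),
                        dims = c(16, 16, 16))
  same <- resampleGrid(m, m)
  expect_identical(dim(gridValues(same)), dim(gridValues(m)))
  expect_lt(max(abs(gridValues(same) - gridValues(m))), 1e-12)

  const <- DensityGrid(array(3.7, c(10, 10, 10)))
  t2 <- resampleGrid(const, list(origin = c(1.3, 2.1, 0.7),
                                 spacing = 0.9, dims = c(5, 5, 5)))
  expect_lt(max(abs(gridValues(t2) - 3.7)), 1e-12)

  ramp <- DensityGrid(array(rep(0:9, each = 1), c(10, 10, 10)) * 0 +
                        outer(outer(0:9, rep(1, 10)), rep(1, 10)) * 2 +
                        aperm(outer(outer(0:9, rep(1, 10)), rep(1, 10)),
                              c(2, 1, 3)) * 0.5)
  t3 <- resampleGrid(ramp, list(origin = c(1.25, 2.5, 3.75),
                                spacing = 0.5, dims = c(8, 8, 8)))
  expected <- outer(outer(1.25 + (0:7) * 0.5, rep(1, 8)), rep(1, 8)) * 2 +
    aperm(outer(outer(2.5 + (0:7) * 0.5, rep(1, 8)), rep(1, 8)),
          c(2, 1, 3)) * 0.5
  expect_lt(max(abs(gridValues(t3) - expected)), 1e-10)

  expect_error(resampleGrid(const, list(origin = c(100, 0, 0),
                                        spacing = 1, dims = c(4, 4, 4))),
               class = "rw_geometry_error")
})

test_that("symmetry averaging matches its analytic oracle", {
  expect_equal(symmetryIncrement(14), 360 / 14)
  blob <- list(center = c(32, 42, 32), sigma = 4, amplitude = 1)
  m1 <- makeSymmetricMap(1, list(blob), dims = c(64, 64, 64))
  expect_identical(gridValues(symmetryAverage(m1, 1)), gridValues(m1))

  avg <- symmetryAverage(m1, 14)
  oracle <- makeSymmetricMap(14, list(modifyList(blob,
                                                 list(amplitude = 1 / 14))),
                             dims = c(64, 64, 64))
  peak <- max(gridValues(oracle))
  expect_lt(max(abs(gridValues(avg) - gridValues(oracle))), 0.01 * peak)

  # an exactly symmetric map is a fixed point (within interpolation error)
  msym <- makeSymmetricMap(14, list(blob), dims = c(64, 64, 64))
  a1 <- symmetryAverage(msym, 14)
  expect_lt(max(abs(gridValues(a1) - gridValues(msym))),
            0.01 * max(gridValues(msym)))
  # idempotence within twice the interpolation tolerance
  a2 <- symmetryAverage(symmetryAverage(m1, 14), 14)
  expect_lt(max(abs(gridValues(a2) - gridValues(avg))),
            0.02 * max(gridValues(avg)))
  # total density conservation for well-contained support
  expect_lt(abs(sum(gridValues(avg)) - sum(gridValues(m1))) /
              sum(gridValues(m1)), 0.01)
  expect_error(symmetryAverage(m1, 0), class = "rw_spec_error")
})

test_that("the symmetry axis search finds constructed ground truth", {
  m <- makeSymmetricMap(3, list(list(center = c(16, 22, 16), sigma = 3,
                                     amplitude = 1)),
                        dims = c(32, 32, 32))
  est <- estimateSymmetryAxis(m, 3, tiltSearch = 1, step = 0.5)
  expect_equal(est$tilt, c(0, 0))
  expect_gt(est$score, 0.999)

  # the same map tilted 1 degree about x is recovered within one step
  pts <- ringweld:::latticePoints(gridOrigin(m), gridSpacing(m),
                                  gridDims(m))
  src <- rotateAboutAxis(pts, c(15.5, 15.5, 15.5), c(1, 0, 0), -1)
  tilted <- DensityGrid(array(ringweld:::trilinearSample(m, src),
                              dim = gridDims(m)))
  est2 <- estimateSymmetryAxis(tilted, 3, tiltSearch = 2, step = 0.5)
  expect_lt(abs(est2$tilt[1] - 1), 0.51)

  # C2 fixture: the true axis outscores a 5-degree tilt
  m2 <- makeSymmetricMap(2, list(list(center = c(16, 21, 16), sigma = 3,
                                      amplitude = 1)),
                         dims = c(32, 32, 32))
  estTrue <- estimateSymmetryAxis(m2, 2, tiltSearch = 0, step = 1)
  scoreAt <- function(tiltX) {
    dir <- c(ringweld:::rotationMatrixAxis(c(1, 0, 0), tiltX) %*%
               c(0, 0, 1))
    src <- rotateAboutAxis(pts, estTrue$axisPoint, dir, -180)
    stats::cor(as.numeric(gridValues(m2)),
               ringweld:::trilinearSample(m2, src))
  }
  expect_gt(scoreAt(0), scoreAt(5))
  expect_error(estimateSymmetryAxis(DensityGrid(array(1, c(8, 8, 8))), 2),
               class = "rw_degenerate_error")
})

test_that("masks threshold strictly above the level", {
  v <- array(0, c(5, 5, 4))
  v[1:4, 1, 1] <- 1
  v[5, 5, 4] <- 0.8
  g <- DensityGrid(v)
  expect_equal(sum(gridValues(buildMask(g, 0.8))), 4)  # strict >
  expect_equal(sum(gridValues(buildMask(g, -1))), 100)
  expect_equal(sum(gridValues(buildMask(g, 2))), 0)
})

test_that("RSCC is a masked Pearson correlation with its invariances", {
  set.seed(2)
  a <- DensityGrid(array(runif(1000), c(10, 10, 10)))
  b <- DensityGrid(array(runif(1000), c(10, 10, 10)))
  expect_equal(rscc(a, a), 1)
  expect_equal(rscc(a, DensityGrid(2 * gridValues(a) + 7)), 1,
               tolerance = 1e-10)
  expect_equal(rscc(a, DensityGrid(-gridValues(a))), -1,
               tolerance = 1e-10)
  expect_equal(rscc(a, b), rscc(b, a), tolerance = 1e-12)
  expect_equal(rscc(a, b),
               oracleDirectPearson(as.numeric(gridValues(a)),
                                   as.numeric(gridValues(b))),
               tolerance = 1e-12)
  flat <- DensityGrid(array(1, c(10, 10, 10)))
  expect_error(rscc(a, flat), class = "rw_degenerate_error")
  one <- array(0, c(10, 10, 10))
  one[1] <- 1
  m <- buildMask(DensityGrid(one), 0.5)
  expect_error(rscc(a, b, m), class = "rw_mask_error")  # < 2 voxels
})
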