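test_that("the ring region is the azimuth-ordered outer-centroid polygon", {
  ring <- makeReferenceRing(ringSpec())
  rg <- ringRegion(ring)
  expect_equal(nrow(rg@polygon), 14)
  expect_equal(colMeans(rg@polygon), c(12, 9), tolerance = 1e-9)
  # regular 14-gon: all vertices at the outer radius
  r <- sqrt(rowSums(sweep(rg@polygon, 2, c(12, 9))^2))
  expect_lt(max(abs(r - 2.6)), 1e-9)
  expect_equal(rg@zMid, 6, tolerance = 1e-12)

  # two half-rings 5 nm apart: one simple polygon spanning the gap
  asm <- makeAssemblySystem(separation = 5,
                            plug = plugSpec(0, 0, bulkDensity = 0))
  rg2 <- ringRegion(asm$system)
  expect_equal(nrow(rg2@polygon), 14)
  expect_gt(diff(range(rg2@polygon[, 1])), 5 + 2 * 2.6 - 0.5)

  few <- makeReferenceRing(ringSpec(nProtomers = 3))
  sub <- BeadSystem(coords = coords(few)[1:12, ],
                    kind = beadKind(few)[1:12], box = boxDims(few),
                    protomer = protomerIndex(few)[1:12],
                    molecule = moleculeIndex(few)[1:12])
  expect_error(ringRegion(sub), class = "rw_geometry_error")
})

test_that("lipid classification agrees with the winding-number oracle", {
  ring <- makeReferenceRing(ringSpec())
  rg <- ringRegion(ring)
  set.seed(5)
  pts <- cbind(runif(1e4, 6, 18), runif(1e4, 3, 15))
  got <- pointInPolygon(pts, rg@polygon)
  expect_identical(got, oracleWindingInside(pts, rg@polygon))
  # boundary vertex counts as inside
  expect_true(pointInPolygon(rg@polygon[3, , drop = FALSE], rg@polygon))
})

test_that("classification partitions lipids and respects leaflet sign", {
  asm <- makeAssemblySystem(separation = 0, plug = plugSpec(6, 9))
  s <- asm$system
  rg <- ringRegion(s)
  cls <- classifyLipids(s, rg)
  nLip <- length(unique(moleculeIndex(s)[beadKind(s) == "lipid_head"]))
  expect_equal(nrow(cls), nLip)               # every lipid classified
  expect_true(all(cls$inside %in% c(TRUE, FALSE)))
  expect_setequal(unique(cls$leaflet), c("loop_side", "nc_side"))
  cnt <- countEncapsulated(staticTrajectory(s))
  expect_equal(unname(cnt$final), c(6, 9, 15))
  expect_true(all(cnt$perFrame$nTotal ==
                    cnt$perFrame$nLoop + cnt$perFrame$nNC))

  # all lipids scripted outside -> zero counts
  scr <- data.frame(lipid = 1:3, leaflet = "loop_side", start = NA,
                    end = NA)
  trOut <- makeScriptedTrajectory(nFrames = 3, dtPs = 100,
                                  lipidScript = scr)
  expect_equal(unname(countEncapsulated(trOut)$final), c(0, 0, 0))
})

test_that("residence records follow the duration and censoring rules", {
  # inside frames 10..19 at 1 ns spacing -> one uncensored 10 ns record
  tr <- makeScriptedTrajectory(nFrames = 30, dtPs = 1000,
    lipidScript = data.frame(lipid = 1, leaflet = "loop_side",
                             start = 10, end = 19))
  rt <- residenceTimes(tr)
  expect_equal(rt$records$duration, 10000)
  expect_false(rt$records$censored)
  expect_equal(unname(rt$summary["meanDuration"]), 10000)

  # inside only the final frame -> censored, excluded from the summary
  tr2 <- makeScriptedTrajectory(nFrames = 10, dtPs = 1000,
    lipidScript = data.frame(lipid = 1, leaflet = "nc_side",
                             start = 10, end = 10))
  rt2 <- residenceTimes(tr2)
  expect_true(rt2$records$censored)
  expect_equal(unname(rt2$summary["n"]), 0)
  expect_equal(unname(residenceTimes(tr2,
                        includeCensored = TRUE)$summary["n"]), 1)

  # durations can never exceed the trajectory span
  scr <- data.frame(lipid = 1:4, leaflet = "loop_side",
                    start = c(1, 3, 8, 2), end = c(6, 9, 10, 10))
  tr3 <- makeScriptedTrajectory(nFrames = 10, dtPs = 500,
                                lipidScript = scr)
  rt3 <- residenceTimes(tr3, includeCensored = TRUE)
  span <- diff(range(frameTimes(tr3))) + 500
  expect_true(all(rt3$records$duration <= span))
})

test_that("irregular frame spacing uses per-gap time steps", {
  scr <- data.frame(lipid = 1, leaflet = "loop_side", start = 2, end = 3)
  tr <- makeScriptedTrajectory(nFrames = 5, dtPs = 1000,
                               lipidScript = scr)
  tr@times <- c(0, 1000, 2000, 5000, 6000)  # stretched gap after exit
  rt <- residenceTimes(tr)
  # inside at t = 1000..2000; the gap after frame 3 is 3000 ps
  expect_equal(rt$records$duration, (2000 + 3000) - 1000)
})

test_that("extrusion events are debounced and direction-tagged", {
  leavers <- data.frame(lipid = 1:3,
                        leaflet = c("nc_side", "nc_side", "loop_side"),
                        start = 1, end = c(49, 30, 40))
  tr <- makeScriptedTrajectory(nFrames = 80, dtPs = 1000,
                               lipidScript = leavers)
  ev <- detectExtrusions(tr)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$frame, c(50, 31, 41))
  expect_equal(ev$direction, c("nc_side", "nc_side", "loop_side"))

  flicker <- data.frame(lipid = c(1, 1), leaflet = "loop_side",
                        start = c(5, 12), end = c(9, 80))
  tr2 <- makeScriptedTrajectory(nFrames = 80, dtPs = 1000,
                                lipidScript = flicker)
  expect_equal(nrow(detectExtrusions(tr2, debounce = 10)), 0)
  # with a 1-frame debounce the same excursion is an event
  expect_equal(nrow(detectExtrusions(tr2, debounce = 1)), 1)
})

test_that("contact series count molecules, not beads, within 4 A", {
  sites <- matrix(c(12, 9, 6.5, 12, 11.5, 6.5), 2, 3, byrow = TRUE)
  ws <- data.frame(water = c(1, 2), frame = c(2, 2), site = c(1, 1),
                   distA = c(3.9, 4.1))
  tr <- makeScriptedTrajectory(nFrames = 3, dtPs = 100, waterScript = ws,
                               sites = sites)
  cs <- contactSeries(tr)
  byFrame <- cs[cs$site == cs$site[1], ]
  expect_equal(byFrame$count, c(0, 1, 0))  # 3.9 in, 4.1 out
  expect_error(contactSeries(tr, sites = integer(0)),
               class = "rw_selection_error")

  # two beads of one molecule within the cutoff still count once
  sys <- BeadSystem(
    coords = rbind(c(5, 5, 5), c(5.2, 5, 5), c(5, 5.2, 5)),
    kind = c("site", "lipid_head", "lipid_tail"), box = c(10, 10, 10),
    molecule = c(0L, 1L, 1L), leaflet = c("none", "loop_side",
                                          "loop_side"))
  cs2 <- contactSeries(staticTrajectory(sys), sites = 1,
                       solvent = c(2, 3), cutoffA = 4)
  expect_equal(cs2$count, 1)
})

test_that("z profiles are normalised half-open histograms", {
  sys <- BeadSystem(coords = cbind(1, 1, rep(2.0, 5)),
                    kind = rep("water", 5), box = c(4, 4, 6),
                    molecule = 0:4)
  pr <- zProfile(staticTrajectory(sys), "water", binWidth = 0.1)
  occ <- pr[pr$density > 0, ]
  expect_equal(nrow(occ), 1)
  expect_equal(c(occ$zLow, occ$zHigh), c(2.0, 2.1))
  expect_equal(sum(pr$density) * 0.1, 1, tolerance = 1e-10)

  # uniform beads give a flat profile within the sampling-noise bound
  set.seed(8)
  nU <- 5000
  sysU <- BeadSystem(coords = cbind(1, 1, runif(nU, 0, 6)),
                     kind = rep("water", nU), box = c(4, 4, 6),
                     molecule = seq_len(nU) - 1L)
  prU <- zProfile(staticTrajectory(sysU), "water", binWidth = 0.5)
  pBin <- 0.5 / 6
  se <- sqrt(pBin * (1 - pBin) / nU)
  expect_true(all(abs(prU$density * 0.5 - pBin) < 4 * se))
})

test_that("plug displacement recovers constructed shifts", {
  base <- rbind(
    data.frame(lipid = 1:6, leaflet = rep(c("loop_side", "nc_side"), 3),
               start = 1, end = 100),
    data.frame(lipid = 7:12, leaflet = rep(c("loop_side", "nc_side"), 3),
               start = NA, end = NA))
  exact <- makeScriptedTrajectory(nFrames = 100, dtPs = 100,
                                  lipidScript = base,
                                  insideZShift = 0.3)
  dz <- plugDisplacement(exact)
  expect_equal(unname(dz), c(0.3, 0.3), tolerance = 1e-9)

  base10 <- base
  base10$end[!is.na(base10$end)] <- 10
  flatTr <- makeScriptedTrajectory(nFrames = 10, dtPs = 100,
                                   lipidScript = base10)
  expect_equal(unname(plugDisplacement(flatTr)), c(0, 0),
               tolerance = 1e-9)

  onlyIn <- makeScriptedTrajectory(nFrames = 5, dtPs = 100,
    lipidScript = data.frame(lipid = 1, leaflet = "loop_side", start = 1,
                             end = 5))
  expect_error(plugDisplacement(onlyIn), class = "rw_degenerate_error")
})
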