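test_that("force terms follow their closed forms", {
  pp <- simParams()
  # Hooke's law: one protomer bead displaced 1 nm from its reference
  sys <- singleBeadWell(at = c(3, 3, 3))
  ref <- singleBeadWell(at = c(4, 3, 3))
  F <- computeForces(sys, ref, kBias = 0.01, params = pp)
  expect_equal(as.numeric(F[1, ]), c(0.01, 0, 0), tolerance = 1e-12)

  # pair force vanishes beyond the contact distance, and obeys Newton's
  # third law within it
  two <- function(d) BeadSystem(coords = rbind(c(2, 2, 2),
                                               c(2 + d, 2, 2)),
                                kind = rep("water", 2), box = c(8, 8, 8),
                                molecule = 0:1)
  expect_equal(max(abs(computeForces(two(0.5), params = pp))), 0)
  Fc <- computeForces(two(0.25), params = pp)
  expect_gt(Fc[2, 1], 0)  # repulsive
  expect_lt(max(abs(Fc[1, ] + Fc[2, ])), 1e-10)
})

test_that("analytic forces equal the numeric potential gradient", {
  pp <- simParams()
  fx <- mixedTestSystem(seed = 1)
  F <- computeForces(fx$system, fx$reference, kBias = 2, params = pp)
  G <- oracleNumericForces(fx$system, fx$reference, 2, pp)
  expect_lt(max(abs(F - G) / pmax(1, abs(F))), 1e-6)
})

test_that("the Brownian update is exact in the deterministic limit", {
  pp <- simParams(temperature = 0, gamma = 50, dt = 0.1)
  sys <- BeadSystem(coords = matrix(c(3, 3, 3), 1, 3), kind = "water",
                    box = c(8, 8, 8), molecule = 0L)
  Fext <- matrix(c(10, -5, 2), 1, 3)
  s2 <- stepBrownian(sys, Fext, pp)
  expect_equal(coords(s2)[1, ] - coords(sys)[1, ],
               as.numeric(Fext / 50 * 0.1), tolerance = 1e-12)

  # compiled path agrees with the reference update: bead in a harmonic
  # well at T = 0 relaxes identically
  well <- singleBeadWell(at = c(3.5, 3, 3))
  ref <- singleBeadWell(at = c(3, 3, 3))
  st <- runStage(well, ref, kBias = 10, duration = pp@dt, params = pp,
                 saveEvery = pp@dt, checkInterval = pp@dt, seed = 1)
  Fbias <- computeForces(well, ref, 10, pp)
  set.seed(1)
  rRef <- stepBrownian(well, Fbias, pp)
  expect_equal(coords(st$finalSystem), coords(rRef), tolerance = 1e-12)
})

test_that("rigid bodies never deform", {
  pp <- simParams()
  asm <- makeAssemblySystem(ringSpec(nProtomers = 3, box = c(10, 10, 10)),
                            plugSpec(1, 1, bulkDensity = 0.5),
                            separation = 2)
  st <- runStage(asm$system, asm$reference, kBias = 5, duration = 400,
                 params = pp, saveEvery = 400, checkInterval = 10,
                 seed = 2)
  s <- st$finalSystem
  for (p in 0:2) {
    rows <- which(protomerIndex(s) == p)
    d0 <- dist(coords(asm$system)[rows, ])
    d1 <- dist(coords(s)[rows, ])
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
  # lipid rods stay intact too
  m <- moleculeIndex(s)[beadKind(s) == "lipid_head"][1]
  rows <- which(moleculeIndex(s) == m)
  expect_lt(max(abs(dist(coords(s)[rows, ]) -
                      dist(coords(asm$system)[rows, ]))), 1e-9)
})

test_that("stage bookkeeping saves the promised frames", {
  pp <- simParams()
  well <- singleBeadWell()
  st <- runStage(well, well, kBias = 1, duration = 200, params = pp,
                 saveEvery = 20, checkInterval = 10, seed = 1)
  expect_equal(nFrames(st$trajectory), 10)
  expect_equal(frameTimes(st$trajectory), seq(20, 200, by = 20))
  expect_equal(st$rmsdTrace$time, seq(0, 200, by = 10))
})

test_that("identical seeds give bit-identical trajectories", {
  pp <- simParams()
  asm <- makeAssemblySystem(ringSpec(nProtomers = 4, box = c(10, 10, 10)),
                            plugSpec(1, 1, bulkDensity = 0.5),
                            separation = 2)
  a <- runStage(asm$system, asm$reference, 10, 20, pp, saveEvery = 2,
                checkInterval = 2, seed = 11)
  b <- runStage(asm$system, asm$reference, 10, 20, pp, saveEvery = 2,
                checkInterval = 2, seed = 11)
  expect_identical(coords(a$trajectory), coords(b$trajectory))
  expect_identical(a$rmsdTrace, b$rmsdTrace)
})

test_that("a strong restraint pulls a perturbed ring monotonically home", {
  pp <- simParams()
  ring <- makeReferenceRing(ringSpec())
  pert <- ring
  x <- coords(ring)
  x[, 1] <- x[, 1] + 0.1  # 1 Angstrom uniform displacement
  coords(pert) <- x
  st <- runStage(pert, ring, kBias = 1000, duration = 4, params = pp,
                 saveEvery = 4, checkInterval = 0.2, seed = 3)
  tr <- st$rmsdTrace$rmsd
  sm <- stats::filter(tr, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.05))
  expect_lt(tail(tr, 1), 1)
})

test_that("divergent dynamics fail loudly, naming the step", {
  pp <- simParams(dt = 50)  # absurd timestep
  sys <- BeadSystem(coords = rbind(c(2, 2, 2), c(2.3, 2, 2)),
                    kind = rep("water", 2), box = c(8, 8, 8),
                    molecule = 0:1)
  expect_error(
    runStage(sys, singleBeadWell(), kBias = 0, duration = 500,
             params = pp, seed = 1),
    "step", class = "rw_divergence_error")
})

test_that("the full protocol classifies a pre-assembled system instantly", {
  pp <- simParams()
  asm <- makeAssemblySystem(ringSpec(nProtomers = 4, box = c(10, 10, 10)),
                            plugSpec(1, 1, bulkDensity = 0.3),
                            separation = 0)
  proto <- biasProtocol(weakMaxDuration = 50,
                        strongStages = cbind(k = c(10, 100),
                                             duration = c(5, 5)))
  res <- runAssemblyProtocol(asm$system, asm$reference, proto, pp,
                             seed = 1)
  expect_equal(res@convergenceTime, 0)
  expect_equal(res@outcome, "assembled")
  expect_equal(res@nTotal, res@nLoop + res@nNC)
})
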