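# The synthetic generator itself: wall construction, equilibrium
# statistics against Poisson/Boltzmann theory, telegraph dynamics.

test_that("buildWall realizes the requested geometry deterministically", {
  cyl <- syntheticPoreModel(mouthRadius = 0.4, waistRadius = 0.4,
                            waistLength = 6, rampLength = 0.01)
  wall <- buildWall(cyl)
  a <- wall@atoms
  axDist <- sqrt(a$x^2 + a$y^2)
  expect_lt(max(abs(axDist - (0.4 + 0.15))), 1e-9)   # all atoms equidistant

  hg <- syntheticPoreModel()   # waist 0.16 nm
  wallH <- buildWall(hg)
  aH <- wallH@atoms
  openR <- min(sqrt(aH$x^2 + aH$y^2) - 0.15)
  expect_lt(abs(openR - 0.16), hg@wallSpacing / 2)

  expect_identical(buildWall(hg)@atoms, wallH@atoms)  # same seed, same wall
  expect_error(buildWall(syntheticPoreModel(wallSpacing = 0.2)),
               "too coarse")
})

test_that("equilibrium occupancy follows the Poisson expectation", {
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01)
  nF <- 2000
  traj <- simulateEquilibrium(mod, nFrames = nF, frameDt = 0.01, seed = 23)
  counts <- groundTruth(traj)$perFrameCounts
  M <- groundTruth(traj)$expectedCount
  expect_equal(M, 33.3 * pi * 0.5^2 * 6, tolerance = 0.001)
  se <- sqrt(M / nF)
  expect_lt(abs(mean(counts) - M), 3 * se)
  # the trajectory rows agree with the logged counts
  expect_equal(nrow(traj@coords), sum(counts))
})

test_that("a 2 kBT step depletes the gate by the Boltzmann factor", {
  Ustep <- function(s) ifelse(abs(s) < 0.5, 2, 0)
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01, U = Ustep)
  traj <- simulateEquilibrium(mod, nFrames = 2000, frameDt = 0.01, seed = 29)
  s <- -traj@coords$z
  nGate <- sum(abs(s) < 0.4)
  nRef <- sum(abs(s) > 1 & abs(s) < 2)
  ratio <- (nGate / 0.8) / (nRef / 2)
  relSE <- sqrt(1 / nGate + 1 / nRef)
  expect_lt(abs(ratio - exp(-2)), 3 * exp(-2) * relSE)
})

test_that("equilibrium frames are reproducible under a fixed seed", {
  mod <- syntheticPoreModel()
  t1 <- simulateEquilibrium(mod, nFrames = 1, frameDt = 0.01, seed = 5)
  t2 <- simulateEquilibrium(mod, nFrames = 1, frameDt = 0.01, seed = 5)
  expect_identical(t1@coords, t2@coords)
  t3 <- simulateEquilibrium(mod, nFrames = 1, frameDt = 0.01, seed = 6)
  expect_false(identical(t1@coords, t3@coords))
})

test_that("density analysis error halves as frames quadruple", {
  U <- function(s) 2 * exp(-s^2 / (2 * 0.8^2))
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01, U = U)
  pw <- modelPathway(mod)
  err <- function(nF, seed) {
    tr <- simulateEquilibrium(mod, nFrames = nF, frameDt = 0.01, seed = seed)
    dp <- densityProfile(mapToPathway(tr, pw), pw, equilibrationCut = 0)
    fep <- boltzmannInvert(dp)
    ref <- smoothedReferenceG(mod, sCoord(fep), dp@bandwidth)
    interior <- abs(sCoord(fep)) < 2.4
    max(abs(freeEnergy(fep) - ref)[interior])
  }
  e1 <- err(400, 41)
  e2 <- err(1600, 42)
  expect_lt(e2, e1)          # stochastic halving, asserted as a decrease
  expect_lt(e2, 0.15)
})

test_that("permanently wetted kinetics give wetted fraction one", {
  mod <- syntheticPoreModel(kWet = 1, kDry = 0, wetMeanOcc = 3)
  traj <- simulateWettingDynamics(mod, duration = 20, frameDt = 0.05,
                                  seed = 3, initState = "wet")
  pw <- modelPathway(mod)
  ws <- classifyWetting(gateOccupancy(traj, pw, c(-1, 1)))
  expect_equal(wettedFraction(ws), 1)
  expect_length(dwellTimes(ws, "dry"), 0L)
})

test_that("undersampled kinetics are rejected", {
  mod <- syntheticPoreModel(kWet = 2, kDry = 1)
  expect_error(simulateWettingDynamics(mod, 10, frameDt = 0.6),
               "undersampling")
  expect_error(simulateWettingDynamics(mod, 10, frameDt = 1.1),
               "undersampling")
})

test_that("dynamics are reproducible and the event log matches the data", {
  mod <- syntheticPoreModel(kWet = 1, kDry = 1, wetMeanOcc = 3)
  t1 <- simulateWettingDynamics(mod, duration = 30, frameDt = 0.05, seed = 8)
  t2 <- simulateWettingDynamics(mod, duration = 30, frameDt = 0.05, seed = 8)
  expect_identical(t1@coords, t2@coords)
  expect_identical(groundTruth(t1)$events, groundTruth(t2)$events)

  gt <- groundTruth(t1)
  # every event time lies inside the simulated window and in a logged state
  expect_true(all(gt$events$time >= 0 & gt$events$time <= 30))
  expect_true(all(gt$states$end > gt$states$start))
  expect_equal(gt$states$start[-1], head(gt$states$end, -1))
})

test_that("scripted trapped waters are released on schedule", {
  mod <- syntheticPoreModel(kWet = 0, kDry = 0, trappedN = 3L,
                            trappedRelease = c(40, NA, NA))
  traj <- simulateWettingDynamics(mod, duration = 50, frameDt = 0.05,
                                  seed = 12, initState = "dry")
  pw <- modelPathway(mod)
  trk <- trackWaters(traj, c(-1, 1), pw)
  expect_length(trk, 3L)
  exits <- do.call(rbind, lapply(trk, trackEvents))
  exits <- exits[exits$type == "exit", ]
  expect_equal(nrow(exits), 1L)
  expect_equal(exits$time, 40, tolerance = 0.05)
  # the two unreleased waters qualify as trapped residents
  expect_length(trappedWaters(trk, minResidence = 10), 2L)
})
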