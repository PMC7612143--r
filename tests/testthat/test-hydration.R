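# Mapping waters to the pathway coordinate and KDE density profiles.

cylPathway <- function() straightPathway(function(s) rep(0.5, length(s)))

test_that("waters map to s with the z = -s convention and radial cutoff", {
  pw <- cylPathway()
  traj <- framesTrajectory(list(data.frame(
    molId = 1:4,
    x = c(0, 0, 0, 0.9),          # 4th water at radial 0.9 > 1.2 * 0.5
    y = 0,
    z = c(0, 1.0, -0.4, 0))))
  m <- mapToPathway(traj, pw)
  m <- m[order(m$molId), ]
  expect_equal(m$molId, 1:3)                  # outside-cutoff water excluded
  expect_equal(m$s, c(0, -1.0, 0.4), tolerance = 1e-9)
  # a water just inside the cutoff is retained
  traj2 <- framesTrajectory(list(data.frame(molId = 1, x = 0.59, y = 0, z = 0)))
  expect_equal(nrow(mapToPathway(traj2, pw)), 1L)
})

test_that("frames with no waters are tolerated and recorded", {
  pw <- cylPathway()
  traj <- framesTrajectory(list(NULL, data.frame(molId = 1, x = 0, y = 0, z = 0),
                                NULL))
  m <- mapToPathway(traj, pw)
  expect_equal(nrow(m), 1L)
  expect_equal(nrow(attr(m, "frames")), 3L)
})

test_that("a single pinned water yields a unit-mass kernel peaked at s = 0", {
  pw <- cylPathway()
  frames <- replicate(50, data.frame(molId = 1, x = 0, y = 0, z = 0),
                      simplify = FALSE)
  traj <- framesTrajectory(frames, frameDt = 0.1)
  dp <- densityProfile(mapToPathway(traj, pw), pw, bandwidth = 0.14,
                       equilibrationCut = 0)
  lam <- dp@lambda
  dg <- diff(sCoord(dp)[1:2])
  expect_equal(sum((lam[-1] + lam[-length(lam)]) / 2) * dg, 1.0,
               tolerance = 0.01)
  expect_lt(abs(sCoord(dp)[which.max(lam)]), dg)
  # conversion to number density uses the local cross-section
  expect_equal(max(densityValues(dp)), max(lam) / (pi * 0.5^2),
               tolerance = 1e-9)
})

test_that("an empty gate gives zero density across the gate", {
  pw <- cylPathway()
  frames <- replicate(20, data.frame(molId = 1:2, x = 0, y = 0,
                                     z = c(2.5, -2.5)), simplify = FALSE)
  traj <- framesTrajectory(frames, frameDt = 0.1)
  dp <- densityProfile(mapToPathway(traj, pw), pw, equilibrationCut = 0)
  gate <- abs(sCoord(dp)) <= 1
  expect_true(all(densityValues(dp)[gate] == 0))
})

test_that("the KDE conserves mass and is bandwidth-monotone", {
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01,
                            U = function(s) 1.5 * exp(-s^2))
  traj <- simulateEquilibrium(mod, nFrames = 300, frameDt = 0.02, seed = 21)
  pw <- modelPathway(mod)
  mapped <- mapToPathway(traj, pw)
  maxima <- c()
  for (bw in c(0.08, 0.14, 0.2, 0.3)) {
    dp <- densityProfile(mapped, pw, bandwidth = bw, equilibrationCut = 0)
    expect_equal(dp@metadata$lambdaIntegral, dp@meanCount,
                 tolerance = 0.01)
    maxima <- c(maxima, max(dp@lambda))
  }
  expect_true(all(diff(maxima) <= 1e-9))
})

test_that("shifting the equilibration cut in a stationary trajectory is benign", {
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01)
  traj <- simulateEquilibrium(mod, nFrames = 800, frameDt = 0.02, seed = 4)
  pw <- modelPathway(mod)
  mapped <- mapToPathway(traj, pw)
  dpA <- densityProfile(mapped, pw, equilibrationCut = 0)
  dpB <- densityProfile(mapped, pw, equilibrationCut = 4)  # drops 25 %
  seA <- profileSD(dpA) / sqrt(nFrames(dpA))
  seB <- profileSD(dpB) / sqrt(nFrames(dpB))
  se <- sqrt(seA^2 + seB^2)
  expect_true(all(abs(densityValues(dpA) - densityValues(dpB)) <= 3 * se))
  expect_error(densityProfile(mapped, pw, equilibrationCut = 1e6),
               "equilibration cut")
})

test_that("repeat averaging gives pointwise means and population SDs", {
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01)
  pw <- modelPathway(mod)
  traj <- simulateEquilibrium(mod, nFrames = 50, frameDt = 0.02, seed = 9)
  dp <- densityProfile(mapToPathway(traj, pw), pw, equilibrationCut = 0)

  same <- averageOverRepeats(list(dp, dp))
  expect_equal(densityValues(same), densityValues(dp))
  expect_true(all(profileSD(same) == 0))
  expect_equal(nFrames(same), 2L * nFrames(dp))

  # constructed two-repeat case: densities 0 and 10 -> mean 5, SD 5
  mk <- function(v) {
    g <- seq(-1, 1, by = 0.5)
    new("DensityProfile", sGrid = g, density = rep(v, 5), sd = rep(0, 5),
        sdType = "frames", lambda = rep(v * pi * 0.25, 5),
        radiusGrid = rep(0.5, 5), bandwidth = 0.14, nFrames = 10L,
        meanCount = v, repeatDensity = matrix(rep(v, 5), 1),
        missing = rep(FALSE, 5))
  }
  avg <- averageOverRepeats(list(mk(0), mk(10)))
  expect_equal(densityValues(avg), rep(5, 5))
  expect_equal(profileSD(avg), rep(5, 5))   # population SD
  expect_error(averageOverRepeats(list(dp, mk(1))), "identical s grid")
})
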