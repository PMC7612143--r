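# Boltzmann inversion, barrier extraction and closed-form energetics.

flatProfile <- function(n0 = 33.3, sd = 0) {
  g <- seq(-3, 3, by = 0.02)
  new("DensityProfile", sGrid = g, density = rep(n0, length(g)),
      sd = rep(sd, length(g)), sdType = "frames",
      lambda = rep(n0 * pi * 0.25, length(g)),
      radiusGrid = rep(0.5, length(g)), bandwidth = 0.14, nFrames = 100L,
      meanCount = n0, repeatDensity = matrix(rep(n0, length(g)), 1),
      missing = rep(FALSE, length(g)))
}

test_that("inversion normalizes flat profiles to zero and is exact on dips", {
  fep <- boltzmannInvert(flatProfile())
  expect_true(all(abs(freeEnergy(fep)) < 1e-12))

  dp <- flatProfile()
  i0 <- which.min(abs(sCoord(dp)))
  dp@density[i0] <- 33.3 * exp(-2)
  dp@repeatDensity[1, i0] <- dp@density[i0]
  fep <- boltzmannInvert(dp)
  expect_equal(freeEnergy(fep)[i0], 2.0, tolerance = 1e-6)
})

test_that("zero densities are capped and flagged; bad inputs error", {
  dp <- flatProfile()
  gate <- abs(sCoord(dp)) < 0.3
  dp@density[gate] <- 0
  dp@repeatDensity[1, gate] <- 0
  fep <- boltzmannInvert(dp, cap = 25)
  expect_true(all(fep@capped[gate]))
  expect_true(all(freeEnergy(fep)[gate] == 25))

  dpNeg <- flatProfile(); dpNeg@density[5] <- -1
  expect_error(boltzmannInvert(dpNeg), "negative density")
  dp0 <- flatProfile(1e-300)
  dp0@density[] <- 0; dp0@repeatDensity[] <- 0
  expect_error(boltzmannInvert(dp0), "zero bulk density")
  expect_error(boltzmannInvert(flatProfile(), bulkInterval = c(-10, 10)),
               "within the profile grid")
})

test_that("inversion round-trips the density and absorbs constant scalings", {
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01,
                            U = function(s) 2 * exp(-s^2))
  traj <- simulateEquilibrium(mod, nFrames = 200, frameDt = 0.02, seed = 13)
  pw <- modelPathway(mod)
  dp <- densityProfile(mapToPathway(traj, pw), pw, equilibrationCut = 0)
  fep <- boltzmannInvert(dp)
  back <- exp(-freeEnergy(fep)) * fep@normConst
  ok <- !fep@capped
  expect_equal(back[ok], densityValues(dp)[ok], tolerance = 1e-12)

  dp3 <- dp
  dp3@density <- dp@density * 3
  dp3@sd <- dp@sd * 3
  dp3@lambda <- dp@lambda * 3
  dp3@repeatDensity <- dp@repeatDensity * 3
  dp3@meanCount <- dp@meanCount * 3
  fep3 <- boltzmannInvert(dp3)
  expect_equal(freeEnergy(fep3), freeEnergy(fep), tolerance = 1e-12)
})

test_that("barrier extraction returns the gate maximum and repeat spread", {
  fep0 <- boltzmannInvert(flatProfile())
  b0 <- barrierHeight(fep0, c(-1, 1))
  expect_equal(b0$barrier, 0, tolerance = 1e-12)

  # constructed profile with a single 13.5 kBT maximum inside the gate
  dp <- flatProfile()
  i0 <- which.min(abs(sCoord(dp) - 0.2))
  dp@density[i0] <- 33.3 * exp(-13.5)
  dp@repeatDensity[1, i0] <- dp@density[i0]
  b <- barrierHeight(boltzmannInvert(dp), c(-1, 1))
  expect_equal(b$barrier, 13.5, tolerance = 1e-6)
  expect_equal(b$sAtMax, 0.2, tolerance = 0.011)
  expect_error(barrierHeight(boltzmannInvert(dp), c(10, 11)),
               "empty gate interval|within the profile grid")
})

test_that("barrier SD across repeats matches the per-repeat spread", {
  mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5,
                            waistLength = 6, rampLength = 0.01,
                            U = function(s) 2 * exp(-s^2 / (2 * 0.7^2)))
  pw <- modelPathway(mod)
  reps <- lapply(1:4, function(i) {
    tr <- simulateEquilibrium(mod, nFrames = 400, frameDt = 0.02,
                              seed = 100 + i)
    densityProfile(mapToPathway(tr, pw), pw, equilibrationCut = 0)
  })
  avg <- averageOverRepeats(reps)
  fep <- boltzmannInvert(avg)
  b <- barrierHeight(fep, c(-1, 1))
  perRep <- b$perRepeat
  expect_equal(length(perRep), 4L)
  expect_equal(b$sd, sqrt(mean((perRep - mean(perRep))^2)), tolerance = 1e-9)
  # the recovered barrier sits near the generating barrier of 2 kBT
  expect_lt(abs(b$barrier - 2), 3 * max(b$sd / sqrt(4), 0.05) + 0.1)
})

test_that("Boltzmann stabilization pools fixed-charge densities by mean", {
  est1 <- stabilizationEnergy(35, c(22, 16), 310)
  expect_equal(round(est1@deltaU, 1), -1.6)
  expect_equal(est1@pooled, 19)

  est2 <- stabilizationEnergy(15, c(0, 6), 310)
  expect_equal(round(est2@deltaU, 1), -4.1)
  expect_equal(est2@deltaU, -0.0083145 * 310 * log(15 / 3), tolerance = 1e-12)

  expect_equal(stabilizationEnergy(12, 12, 300)@deltaU, 0)
  expect_error(stabilizationEnergy(-1, c(1, 2)), "rhoP")
  deg <- stabilizationEnergy(10, c(0, 0), 310)
  expect_true(deg@degenerate)
  expect_identical(deg@deltaU, -Inf)
  # sign property: stabilizing whenever rhoP exceeds every rhoNP
  for (i in 1:20) {
    rp <- 5 + i
    rn <- c(rp - 1, rp - 3)
    expect_lt(stabilizationEnergy(rp, rn, 310)@deltaU, 0)
  }
})

test_that("kBT conversions, cylinder capacity and molecular volume", {
  expect_equal(round(kbtToKJmol(11, 310)), 28)
  expect_equal(round(kbtToKJmol(6, 310)), 15)
  expect_equal(kbtToKJmol(0, 310), 0)
  for (Tk in c(100, 310, 450))
    expect_equal(kbtToKJmol(1, Tk) / Tk, 0.0083145, tolerance = 1e-12)

  cc <- cylinderCapacity(0.5, 2.0, 0.03)
  expect_equal(cc$count, 52.4, tolerance = 0.01)
  expect_equal(cc$rounded, 50)
  nano <- cylinderCapacity(0.16, 0.5, 0.03)
  expect_equal(round(nano$count, 1), 1.3)   # the ~0.04 nm^3 nanocavity
  expect_equal(cylinderCapacity(0.3, 1.1, pi * 0.3^2 * 1.1)$count, 1)

  v <- waterMolecularVolume(0.997, 18.015)
  expect_equal(signif(v, 2), 0.030)
  expect_equal(1 / v, 33.3, tolerance = 0.01)
  expect_equal(waterMolecularVolume(2 * 0.997, 18.015), v / 2)
})

test_that("the Onsager dipole-in-cavity estimate matches direct evaluation", {
  expect_equal(onsagerCavityEnergy(1.85, 0.193, 4, 4), 0)
  # independent constant-by-constant recomputation
  mu <- 1.85 * 3.33564e-30
  a <- 0.193e-9
  kC <- 1 / (4 * pi * 8.8542e-12)
  direct <- -kC * mu^2 / a^3 * ((4 - 1) / (2 * 4 + 1)) * 6.02214e23 / 1000
  got <- onsagerCavityEnergy(1.85, 0.193, 1, 4)
  expect_equal(got, direct, tolerance = 1e-12)
  expect_equal(round(got, 1), -9.6)
  # monotone in mu^2 and in a^3
  expect_lt(onsagerCavityEnergy(2.2, 0.193, 1, 4), got)
  expect_gt(onsagerCavityEnergy(1.85, 0.25, 1, 4), got)
  expect_error(onsagerCavityEnergy(1.85, 0.193, 0.5, 4), ">= 1")
})
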