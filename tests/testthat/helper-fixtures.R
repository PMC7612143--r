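# Shared fixtures and independent oracles, built in code at test time.

# Wall of pseudo-atom rings with centers ON the surface of revolution
# rho(z) (so the open pore radius is rho(z) - vdw). Independent of
# buildWall(), which places centers at rho + vdw.
ringWall <- function(rhoFun, vdw = 0.15, zRange = c(-2, 2), spacing = 0.05) {
  zs <- seq(zRange[1], zRange[2], by = spacing)
  rows <- lapply(seq_along(zs), function(i) {
    z <- zs[i]
    a <- rhoFun(z)
    m <- max(8L, ceiling(2 * pi * a / spacing))
    th <- 2 * pi * (seq_len(m) - 1) / m + (i %% 2) * pi / m
    data.frame(x = a * cos(th), y = a * sin(th), z = z)
  })
  xyz <- do.call(rbind, rows)
  new("PoreStructure",
      atoms = data.frame(id = seq_len(nrow(xyz)), name = "WAL",
                         element = "X", x = xyz$x, y = xyz$y, z = xyz$z,
                         radius = vdw))
}

# Brute-force oracle: the maximal inscribed-sphere radius over a fine 2-D
# grid in the plane z = z0. Direct min-distance scan, no optimizer.
gridScanRadius <- function(structure, z0, halfWidth = 0.25, res = 0.005) {
  a <- structure@atoms
  keep <- abs(a$z - z0) <= 1.5
  xyz <- as.matrix(a[keep, c("x", "y", "z")])
  radii <- a$radius[keep]
  g <- seq(-halfWidth, halfWidth, by = res)
  best <- -Inf
  for (x in g) {
    for (y in g) {
      d <- sqrt((xyz[, 1] - x)^2 + (xyz[, 2] - y)^2 + (xyz[, 3] - z0)^2)
      r <- min(d - radii)
      if (r > best) best <- r
    }
  }
  best
}

# Straight reference pathway along z (s = -z), radius profile R(s).
straightPathway <- function(Rfun, L = 6, step = 0.05) {
  z <- seq(L / 2, -L / 2, by = -step)
  new("Pathway", points = cbind(0, 0, z), s = -z,
      radius = Rfun(-z), axis = c(0, 0, 1), step = step,
      metadata = list(convention = "z = -s"))
}

# Long-format trajectory from a list of per-frame data.frames (molId, x, y, z).
framesTrajectory <- function(frameList, frameDt = 1, persistentIds = TRUE) {
  times <- (seq_along(frameList) - 1) * frameDt
  rows <- lapply(seq_along(frameList), function(i) {
    f <- frameList[[i]]
    if (is.null(f) || !nrow(f)) return(NULL)
    data.frame(time = times[i], molId = f$molId, x = f$x, y = f$y, z = f$z)
  })
  co <- do.call(rbind, rows)
  makeTrajectory(co, times = times, persistentIds = persistentIds)
}

# Gaussian-smoothed reference free energy: the expectation of the KDE
# estimator under the generator's intensity, computed by direct numerical
# convolution with boundary reflection (independent of the package's KDE).
smoothedReferenceG <- function(model, grid, bandwidth) {
  ds <- 0.002
  lo <- min(grid); hi <- max(grid)
  sFine <- seq(lo, hi, by = ds)
  lamFine <- model@nBulk * pi * modelRadius(model, -sFine)^2 *
    exp(-model@U(sFine))
  smooth <- vapply(grid, function(g) {
    w <- dnorm(sFine - g, sd = bandwidth) +
      dnorm(2 * lo - sFine - g, sd = bandwidth) +
      dnorm(2 * hi - sFine - g, sd = bandwidth)
    sum(w * lamFine) * ds
  }, numeric(1))
  nRef <- smooth / (pi * modelRadius(model, -grid)^2)
  mask <- grid <= lo + 0.5 | grid >= hi - 0.5
  g <- -log(nRef / mean(nRef[mask]))
  g - mean(g[mask])   # same bulk recentering as boltzmannInvert()
}
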