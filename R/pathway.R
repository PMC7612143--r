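# Probe-sphere pathway finding (HOLE/CHAP-style): at each slice
# perpendicular to the pore axis the centerline point maximizes the
# inscribed-sphere radius r(p) = min_i(|p - x_i| - r_vdw,i).

# Inscribed-sphere radius at point p given atom coordinate matrix and radii.
.inscribedRadius <- function(p, xyz, radii) {
  d2 <- (xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2
  min(sqrt(d2) - radii)
}

# Deterministic restart jitter: a fixed low-discrepancy spiral keyed by the
# rng seed, so identical seeds give bit-identical pathways without touching
# R's global RNG state.
.jitterPoint <- function(k, radius, seed) {
  ang <- 2 * pi * ((k * 0.6180339887498949 + seed * 0.2654435769) %% 1)
  r <- radius * (0.2 + 0.6 * (k %% 4) / 4)
  c(r * cos(ang), r * sin(ang))
}

# Optimize the in-plane probe position for one slice. The plane passes
# through `center` perpendicular to `axis`; (u, v) span the plane and are
# chosen equivariantly by the caller. Returns list(center, radius).
.optimizeSlice <- function(center, axis, u, v, xyz, radii, searchRadius,
                           maxRestarts, rngSeed, slice) {
  fn <- function(ab) {
    if (sum(ab^2) > searchRadius^2) return(1e3 + sum(ab^2))
    p <- center + ab[1] * u + ab[2] * v
    -.inscribedRadius(p, xyz, radii)
  }
  ctrl <- list(reltol = 1e-12, maxit = 600)
  best <- optim(c(0, 0), fn, method = "Nelder-Mead", control = ctrl)
  k <- 0L
  while (-best$value <= 0 && k < maxRestarts) {
    k <- k + 1L
    st <- .jitterPoint(k, searchRadius, rngSeed)
    cand <- optim(st, fn, method = "Nelder-Mead", control = ctrl)
    if (cand$value < best$value) best <- cand
  }
  if (-best$value <= 0)
    stop(sprintf("probe optimization failed at slice %d: no point with positive inscribed radius after %d restarts",
                 slice, maxRestarts))
  # polish from the incumbent to tighten Nelder-Mead's final simplex
  best <- optim(best$par, fn, method = "Nelder-Mead", control = ctrl)
  list(center = center + best$par[1] * u + best$par[2] * v,
       radius = -best$value)
}

# Rotation-equivariant in-plane basis: u points from the slice center
# toward the (projection of the) nearest atom, v completes the frame.
# Because the reference atom co-rotates with the structure, the whole
# optimization is equivariant under rigid transforms.
.planeBasis <- function(center, axis, xyz) {
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
        (xyz[, 3] - center[3])^2
  w <- xyz[which.min(d2), ] - center
  u <- w - sum(w * axis) * axis
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) {          # degenerate: nearest atom on the axis
    k <- which.min(abs(axis))
    e <- c(0, 0, 0); e[k] <- 1
    u <- e - sum(e * axis) * axis
    nu <- sqrt(sum(u^2))
  }
  u <- u / nu
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

#' Find the permeation pathway through a pore-forming structure
#'
#' Probe-sphere pathway search. The pore axis is estimated as the principal
#' axis of the atom cloud; starting from a seed point inside the lumen the
#' search advances in fixed steps along the axis and, at each slice,
#' maximizes the inscribed-sphere radius
#' \eqn{r(p) = \min_i(|p - x_i| - r_{vdw,i})} over the plane perpendicular
#' to the axis (Nelder-Mead restarted from the previous slice's center,
#' with deterministic jittered restarts keyed by \code{rngSeed}). The
#' pathway terminates at the pore mouths, where the local radius exceeds
#' \code{stopRadius} for \code{stopConsecutive} consecutive slices.
#'
#' The arc-length coordinate s increases toward the intracellular side so
#' that for an axis-aligned pore z = -s up to a constant; s = 0 is placed
#' at the narrowest point (the gate-region midpoint) unless
#' \code{sZero = "seed"}.
#'
#' @param structure a \linkS4class{PoreStructure}.
#' @param seedPoint numeric length-3, a point inside the pore lumen (nm).
#' @param step slice advance along the axis (nm, default 0.05).
#' @param searchRadius maximum in-plane displacement of the centerline
#'   per slice (nm). Kept below step*sqrt(3) so consecutive centerline
#'   points stay within twice the step; the seed slice itself is searched
#'   over a wider 0.5 nm disc.
#' @param stopRadius pore-mouth radius threshold (nm, default 1.0).
#' @param stopConsecutive number of consecutive over-threshold slices that
#'   terminate the search (default 3).
#' @param maxRestarts maximum jittered optimizer restarts per slice.
#' @param rngSeed integer seed for the deterministic restart sequence;
#'   identical seeds give bit-identical pathways.
#' @param sZero "minR" (default) to place s = 0 at the minimum-radius
#'   slice, or "seed" to place it at the seed slice.
#' @param maxSlices hard cap on slices per direction.
#' @return a \linkS4class{Pathway}.
#' @examples
#' mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.5)
#' wall <- buildWall(mod)
#' pw <- findPathway(wall, c(0, 0, 0))
#' range(poreRadius(pw))
#' @export
findPathway <- function(structure, seedPoint, step = 0.05,
                        searchRadius = 0.08, stopRadius = 1.0,
                        stopConsecutive = 3L, maxRestarts = 8L,
                        rngSeed = 1L, sZero = c("minR", "seed"),
                        maxSlices = 500L) {
  stopifnot(is(structure, "PoreStructure"), length(seedPoint) == 3,
            step > 0, searchRadius > 0, stopRadius > 0)
  sZero <- match.arg(sZero)
  a <- structure@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- a$radius

  # principal axis of the atom cloud, deterministic sign
  ctr <- colMeans(xyz)
  ev <- eigen(cov(xyz), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  k <- which.max(abs(axis))
  if (axis[k] < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))

  az <- as.numeric(xyz %*% axis)
  azRange <- range(az)
  win <- stopRadius + 0.5 + max(radii)

  sliceAtoms <- function(t0) {
    keep <- abs(az - t0) <= win
    list(xyz = xyz[keep, , drop = FALSE], radii = radii[keep])
  }

  solveSlice <- function(center, slice, moveRadius = searchRadius) {
    t0 <- sum(center * axis)
    sa <- sliceAtoms(t0)
    if (nrow(sa$xyz) == 0L)
      stop(sprintf("no atoms near slice %d: pathway left the structure", slice))
    b <- .planeBasis(center, axis, sa$xyz)
    .optimizeSlice(center, axis, b$u, b$v, sa$xyz, sa$radii, moveRadius,
                   maxRestarts, rngSeed, slice)
  }

  seed <- as.numeric(seedPoint)
  if (.inscribedRadius(seed, xyz, radii) <= 0)
    stop("seed outside lumen: the largest inscribed sphere at the seed point has radius <= 0")
  # the seed may sit well off the true centerline: allow a wide first search
  first <- tryCatch(solveSlice(seed, 0L, moveRadius = max(searchRadius, 0.5)),
                    error = function(e)
    stop("seed outside lumen: ", conditionMessage(e)))
  if (first$radius <= 0)
    stop("seed outside lumen: inscribed radius at the seed slice is <= 0")
  if (first$radius > stopRadius)
    stop(sprintf("seed is not inside a pore: inscribed radius %.2f nm exceeds the stop radius %.2f nm",
                 first$radius, stopRadius))

  march <- function(dir) {
    centers <- list(); rads <- numeric(0)
    prev <- first$center
    over <- 0L; slice <- 0L
    repeat {
      slice <- slice + 1L
      if (slice > maxSlices) break
      start <- prev + dir * step * axis
      t0 <- sum(start * axis)
      # small margin so the extent check is robust to rotation round-off
      if (t0 > azRange[2] + step - 1e-9 || t0 < azRange[1] - step + 1e-9) break
      res <- solveSlice(start, slice * dir)
      centers[[slice]] <- res$center
      rads[slice] <- res$radius
      prev <- res$center
      over <- if (res$radius > stopRadius) over + 1L else 0L
      if (over >= stopConsecutive) break
    }
    list(centers = centers, radius = rads)
  }

  up <- march(+1)   # toward +axis (increasing z, decreasing s)
  dn <- march(-1)

  pts <- rbind(
    if (length(up$centers)) do.call(rbind, rev(up$centers)) else NULL,
    matrix(first$center, nrow = 1),
    if (length(dn$centers)) do.call(rbind, dn$centers) else NULL)
  rad <- c(rev(up$radius), first$radius, dn$radius)
  if (nrow(pts) < 2L)
    stop("pathway search produced fewer than 2 slices; check seed and stop criterion")

  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  ref <- if (sZero == "minR") which.min(rad) else length(up$radius) + 1L
  s <- s - s[ref]
  dimnames(pts) <- NULL

  new("Pathway", points = pts, s = s, radius = rad, axis = axis,
      step = step,
      metadata = list(seedPoint = seed, rngSeed = as.integer(rngSeed),
                      stopRadius = stopRadius,
                      stopConsecutive = as.integer(stopConsecutive),
                      searchRadius = searchRadius, sZero = sZero,
                      convention = "z = -s"))
}

#' Interpolate the pore radius profile onto a regular grid
#'
#' Linear (hence monotone- and shape-preserving) interpolation of the
#' pathway's R(s) onto the requested s grid.
#'
#' @param pathway a \linkS4class{Pathway}.
#' @param grid numeric s values (nm), all within the pathway s range.
#' @return numeric vector of radii (nm), one per grid point.
#' @examples
#' pw <- new("Pathway", points = cbind(0, 0, c(0, -1)), s = c(0, 1),
#'           radius = c(0.2, 0.4), axis = c(0, 0, 1), step = 1)
#' radiusProfile(pw, 0.5)  # 0.3
#' @export
radiusProfile <- function(pathway, grid) {
  stopifnot(is(pathway, "Pathway"), is.numeric(grid))
  rng <- range(pathway@s)
  if (any(grid < rng[1] - 1e-9) || any(grid > rng[2] + 1e-9))
    stop(sprintf("grid outside the pathway s range [%.3f, %.3f] nm",
                 rng[1], rng[2]))
  approx(pathway@s, pathway@radius, xout = pmin(pmax(grid, rng[1]), rng[2]),
         method = "linear", ties = "ordered")$y
}
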