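# Mapping waters onto the pathway coordinate and KDE density profiles.

# Local unit tangents of the centerline, pointing in the direction of
# increasing s (central differences, one-sided at the ends).
.pathTangents <- function(points) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[1, ] <- points[2, ] - points[1, ]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2L) tg[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tg / sqrt(rowSums(tg^2))
}

#' Map water positions onto the pathway coordinate
#'
#' Assigns each water the arc-length coordinate s of its nearest centerline
#' point, provided its radial (perpendicular) distance from the centerline
#' does not exceed \code{radialCutoffFactor * R(s)}; waters outside that
#' cutoff are excluded as non-pore waters. The pathway's sign convention is
#' inherited: a water displaced by +1 nm in z from the gate center of an
#' axis-aligned pore maps to s = -1 nm.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pathway a \linkS4class{Pathway} in the same coordinate frame.
#' @param radialCutoffFactor dimensionless multiple of the local pore
#'   radius (default 1.2) within which a water counts as a pore water.
#' @return data.frame with columns \code{frame}, \code{time}, \code{molId},
#'   \code{s}, \code{radial} (one row per pore water per frame; frames with
#'   no pore waters simply contribute no rows). The full frame table,
#'   including empty frames, is attached as \code{attr(, "frames")}.
#' @export
mapToPathway <- function(traj, pathway, radialCutoffFactor = 1.2) {
  stopifnot(is(traj, "Trajectory"), is(pathway, "Pathway"),
            radialCutoffFactor > 0)
  if (nrow(pathway@points) < 2L) stop("empty pathway")
  P <- pathway@points
  Tg <- .pathTangents(P)
  R <- pathway@radius
  sPath <- pathway@s
  co <- traj@coords

  frames <- data.frame(frame = seq_along(traj@times) - 1L, time = traj@times)
  out <- vector("list", 0L)
  if (nrow(co)) {
    W <- as.matrix(co[, c("x", "y", "z")])
    n <- nrow(W)
    rp2 <- rowSums(P^2)
    chunk <- max(1L, 200000L %/% nrow(P))
    starts <- seq(1L, n, by = chunk)
    idx <- integer(n); d2min <- numeric(n)
    for (st in starts) {
      en <- min(st + chunk - 1L, n)
      Wc <- W[st:en, , drop = FALSE]
      cross <- Wc %*% t(P)
      D2 <- outer(rowSums(Wc^2), rp2, "+") - 2 * cross
      j <- max.col(-D2, ties.method = "first")
      idx[st:en] <- j
      d2min[st:en] <- D2[cbind(seq_len(nrow(D2)), j)]
    }
    dvec <- W - P[idx, , drop = FALSE]
    axial <- rowSums(dvec * Tg[idx, , drop = FALSE])
    radial <- sqrt(pmax(d2min - axial^2, 0))
    keep <- radial <= radialCutoffFactor * R[idx]
    # continuous s: nearest point's s plus the axial offset along the local
    # tangent (exact for a straight centerline; first-order in curvature
    # otherwise). Waters beyond the pathway ends extrapolate along the end
    # tangents.
    sCont <- sPath[idx] + axial
    out <- data.frame(frame = co$frame[keep], time = co$time[keep],
                      molId = co$molId[keep], s = sCont[keep],
                      radial = radial[keep])
  } else {
    out <- data.frame(frame = integer(0), time = numeric(0),
                      molId = integer(0), s = numeric(0), radial = numeric(0))
  }
  attr(out, "frames") <- frames
  out
}

# Truncated-Gaussian linear density of one frame's s samples on the grid,
# with reflection boundary correction at both grid ends so that kernel
# mass is not lost off the grid (the pathway ends open into bulk, where
# the density is locally flat, which reflection represents exactly).
.frameLambda <- function(sVals, grid, g0, dg, bw, K, nG) {
  lam <- numeric(nG)
  if (!length(sVals)) return(lam)
  gHi <- grid[nG]
  reach <- K * dg
  loRef <- 2 * g0 - sVals[abs(sVals - g0) <= reach]
  hiRef <- 2 * gHi - sVals[abs(sVals - gHi) <= reach]
  sVals <- c(sVals, loRef, hiRef)
  ci <- as.integer(round((sVals - g0) / dg)) + 1L
  offs <- -K:K
  idx <- outer(ci, offs, "+")
  val <- dnorm(grid[pmin(pmax(idx, 1L), nG)] - sVals, sd = bw)
  ok <- idx >= 1L & idx <= nG
  val[!ok] <- 0
  agg <- rowsum(as.vector(val)[as.vector(ok)], as.vector(idx)[as.vector(ok)])
  lam[as.integer(rownames(agg))] <- agg[, 1]
  lam
}

#' Time-averaged water density profile along the pathway
#'
#' Gaussian kernel density estimate of the pathway-mapped water positions.
#' Frames earlier than the equilibration cut are discarded; the remaining
#' frames' s samples are smoothed with a Gaussian kernel (truncated at
#' 4 bandwidths) on a regular grid, giving a per-frame linear density
#' lambda(s) in counts/nm, averaged over frames, and converted to a local
#' number density n(s) = lambda(s) / (pi R(s)^2) in nm^-3. By construction
#' the integral of lambda over the grid equals the mean pore-water count
#' per frame (up to kernel mass lost off the grid ends).
#'
#' @param samples output of \code{\link{mapToPathway}} (its \code{frames}
#'   attribute supplies the full frame list, including empty frames).
#' @param pathway the \linkS4class{Pathway} used for the mapping.
#' @param bandwidth Gaussian KDE bandwidth in nm (default 0.14).
#' @param equilibrationCut discard frames with time < this many ns
#'   (default 10).
#' @param gridSpacing grid spacing in nm (default 0.02).
#' @param truncation kernel truncation in bandwidths (default 4).
#' @return a \linkS4class{DensityProfile} whose pointwise SD is taken over
#'   frames.
#' @export
densityProfile <- function(samples, pathway, bandwidth = 0.14,
                           equilibrationCut = 10, gridSpacing = 0.02,
                           truncation = 4) {
  stopifnot(is(pathway, "Pathway"), bandwidth > 0, gridSpacing > 0)
  frames <- attr(samples, "frames")
  if (is.null(frames))
    stop("samples must carry a 'frames' attribute (use mapToPathway())")
  keep <- frames$time >= equilibrationCut
  if (!any(keep))
    stop(sprintf("all %d frames fall before the %g ns equilibration cut",
                 nrow(frames), equilibrationCut))
  fr <- frames[keep, , drop = FALSE]
  nF <- nrow(fr)
  samp <- samples[samples$frame %in% fr$frame, , drop = FALSE]

  rng <- range(pathway@s)
  grid <- seq(rng[1], rng[2], by = gridSpacing)
  nG <- length(grid); g0 <- grid[1]
  K <- as.integer(ceiling(truncation * bandwidth / gridSpacing))
  Rg <- radiusProfile(pathway, grid)

  sByFrame <- split(samp$s, factor(samp$frame, levels = fr$frame))
  sumL <- numeric(nG); ssL <- numeric(nG)
  for (sv in sByFrame) {
    lam <- .frameLambda(sv, grid, g0, gridSpacing, bandwidth, K, nG)
    sumL <- sumL + lam
    ssL <- ssL + lam^2
  }
  meanL <- sumL / nF
  varL <- pmax(ssL / nF - meanL^2, 0)
  sdL <- sqrt(varL)

  area <- pi * Rg^2
  missing <- Rg <= 0
  dens <- ifelse(missing, NA_real_, meanL / area)
  densSD <- ifelse(missing, NA_real_, sdL / area)
  if (any(missing))
    warning(sprintf("%d grid point(s) have R(s) = 0; density reported as missing there",
                    sum(missing)))
  meanCount <- nrow(samp) / nF
  integ <- sum((meanL[-1] + meanL[-nG]) / 2) * gridSpacing

  new("DensityProfile", sGrid = grid, density = dens, sd = densSD,
      sdType = "frames", lambda = meanL, radiusGrid = Rg,
      bandwidth = bandwidth, nFrames = as.integer(nF),
      meanCount = meanCount,
      repeatDensity = matrix(dens, nrow = 1),
      missing = missing,
      metadata = list(equilibrationCut = equilibrationCut,
                      gridSpacing = gridSpacing, truncation = truncation,
                      lambdaIntegral = integ, frameCounts = nF))
}

#' Average density profiles over independent repeats
#'
#' Pointwise mean and population standard deviation over repeat profiles
#' computed on identical grids with identical bandwidths; frame counts are
#' summed in the metadata.
#'
#' @param profiles list of \linkS4class{DensityProfile} objects.
#' @return a \linkS4class{DensityProfile} whose \code{repeatDensity} holds
#'   one row per repeat and whose SD is the population SD over repeats.
#' @export
averageOverRepeats <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "DensityProfile")))
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (length(p@sGrid) != length(ref@sGrid) ||
        max(abs(p@sGrid - ref@sGrid)) > 1e-9)
      stop("repeat profiles must share an identical s grid")
    if (abs(p@bandwidth - ref@bandwidth) > 1e-12)
      stop("repeat profiles must share an identical bandwidth")
  }
  M <- do.call(rbind, lapply(profiles, function(p) p@density))
  mu <- colMeans(M)
  sdv <- sqrt(colMeans(sweep(M, 2, mu)^2))   # population SD over repeats
  nF <- sum(vapply(profiles, function(p) p@nFrames, integer(1)))
  wts <- vapply(profiles, function(p) p@nFrames, integer(1))
  meanCount <- sum(vapply(profiles, function(p) p@meanCount, numeric(1)) * wts) /
    sum(wts)
  lam <- colSums(do.call(rbind, lapply(profiles, function(p) p@lambda)) * wts) /
    sum(wts)
  new("DensityProfile", sGrid = ref@sGrid, density = mu, sd = sdv,
      sdType = "repeats", lambda = lam, radiusGrid = ref@radiusGrid,
      bandwidth = ref@bandwidth, nFrames = as.integer(nF),
      meanCount = meanCount, repeatDensity = M,
      missing = Reduce(`|`, lapply(profiles, function(p) p@missing)),
      metadata = list(nRepeats = length(profiles),
                      frameCounts = as.integer(wts),
                      gridSpacing = ref@metadata$gridSpacing))
}
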