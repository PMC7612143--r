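# Synthetic pore structures and water trajectories with known ground
# truth: an hourglass wall of pseudo-atoms, equilibrium frames drawn from
# an inhomogeneous Poisson process with intensity
# lambda(s) = n_bulk * pi R(s)^2 * exp(-U(s)), and a two-state
# (wetted/de-wetted) telegraph process with continuous per-water tracks
# and an exact event log.

#' Construct a synthetic pore model
#'
#' Defines the ground truth behind the generator: an hourglass pore whose
#' radius profile is \code{waistRadius} over the central
#' \code{waistLength}, rising smoothly (cosine ramp of length
#' \code{rampLength}) to \code{mouthRadius}; a potential U(s) in kBT; bulk
#' density and temperature; and the two-state gate kinetics. Defaults
#' emulate a tight hydrophobic gate: a 0.16 nm waist over 0.5 nm (a
#' ~0.04 nm^3 nanocavity, just above the 0.03 nm^3 volume of one bulk
#' water), 0.5 nm mouths, 6 nm pore, 33.3 nm^-3 bulk water at 310 K.
#'
#' @param poreLength,mouthRadius,waistRadius,waistLength,rampLength pore
#'   geometry in nm.
#' @param wallSpacing,wallVdw pseudo-atom spacing and van der Waals radius
#'   (nm).
#' @param U function of s (nm) returning the external potential in kBT
#'   (default: identically zero).
#' @param nBulk bulk water number density (nm^-3).
#' @param temperature temperature (K).
#' @param kWet,kDry dry-to-wet and wet-to-dry rates (ns^-1).
#' @param wetMeanOcc,dryMeanOcc mean gate occupancies per state.
#' @param gateInterval gate region in s (nm).
#' @param subcavityWeights relative stationary occupancy weights of the
#'   lower-s and upper-s sub-cavities (gate split at its midpoint).
#' @param walkDiffusion in-gate walker diffusion coefficient (nm^2/ns).
#' @param trappedN,trappedRelease scripted trapped waters: how many start
#'   inside the gate at t = 0 and when each is released (NA = never).
#' @param seed integer generator seed.
#' @return a \linkS4class{SyntheticPoreModel}.
#' @export
syntheticPoreModel <- function(poreLength = 6, mouthRadius = 0.5,
                               waistRadius = 0.16, waistLength = 0.5,
                               rampLength = 1.0, wallSpacing = 0.08,
                               wallVdw = 0.15, U = function(s) rep(0, length(s)),
                               nBulk = 33.3, temperature = 310,
                               kWet = 1, kDry = 1, wetMeanOcc = 3,
                               dryMeanOcc = 0, gateInterval = c(-1, 1),
                               subcavityWeights = c(1, 1),
                               walkDiffusion = 0.1, trappedN = 0L,
                               trappedRelease = numeric(0), seed = 1L) {
  new("SyntheticPoreModel", poreLength = poreLength,
      mouthRadius = mouthRadius, waistRadius = waistRadius,
      waistLength = waistLength, rampLength = rampLength,
      wallSpacing = wallSpacing, wallVdw = wallVdw, U = U, nBulk = nBulk,
      temperature = temperature, kWet = kWet, kDry = kDry,
      wetMeanOcc = wetMeanOcc, dryMeanOcc = dryMeanOcc,
      gateInterval = sort(gateInterval),
      subcavityWeights = subcavityWeights, walkDiffusion = walkDiffusion,
      trappedN = as.integer(trappedN), trappedRelease = trappedRelease,
      seed = as.integer(seed))
}

#' Analytic pore radius profile of a synthetic model
#'
#' The open-pore (probe) radius rho(z) of the hourglass as a function of
#' the axial coordinate z in nm: waist over the central waistLength, a
#' half-cosine ramp to the mouth radius, mouth radius beyond.
#'
#' @param model a \linkS4class{SyntheticPoreModel}.
#' @param z numeric axial coordinates (nm), z = -s.
#' @return numeric radii (nm).
#' @export
modelRadius <- function(model, z) {
  az <- abs(z)
  hw <- model@waistLength / 2
  r <- numeric(length(z))
  ramp <- model@rampLength
  inWaist <- az <= hw
  inRamp <- az > hw & az <= hw + ramp
  r[inWaist] <- model@waistRadius
  t <- (az[inRamp] - hw) / ramp
  r[inRamp] <- model@waistRadius +
    (model@mouthRadius - model@waistRadius) * (1 - cos(pi * t)) / 2
  r[az > hw + ramp] <- model@mouthRadius
  r
}

#' Ground-truth pathway of a synthetic model
#'
#' The exact centerline of the synthetic pore (the z axis), expressed in
#' the package's pathway convention: s = -z, s = 0 at the waist midpoint,
#' R(s) = rho(-s). Useful for analysing synthetic trajectories without
#' running the probe-sphere search.
#'
#' @param model a \linkS4class{SyntheticPoreModel}.
#' @param step centerline point spacing (nm).
#' @return a \linkS4class{Pathway}.
#' @export
modelPathway <- function(model, step = 0.05) {
  L <- model@poreLength
  z <- seq(L / 2, -L / 2, by = -step)
  s <- -z
  pts <- cbind(0, 0, z)
  new("Pathway", points = pts, s = s, radius = modelRadius(model, z),
      axis = c(0, 0, 1), step = step,
      metadata = list(source = "modelPathway", convention = "z = -s"))
}

#' Build a pseudo-atom pore wall
#'
#' Places pseudo-atoms on rings along the pore so that the open (probe)
#' radius equals the model's radius profile: ring centers sit at
#' rho(z) + wallVdw from the axis, rings are wallSpacing apart in z, and
#' atoms are spaced ~wallSpacing around each ring (alternate rings are
#' rotated by half an atom spacing so the wall has no axial seams).
#' Deterministic: the construction uses no randomness and the model seed
#' is only recorded in the metadata.
#'
#' @param model a \linkS4class{SyntheticPoreModel}.
#' @return a \linkS4class{PoreStructure}.
#' @export
buildWall <- function(model) {
  stopifnot(is(model, "SyntheticPoreModel"))
  if (model@wallSpacing >= model@waistRadius)
    stop(sprintf("wall spacing %.3f nm is too coarse to close a %.3f nm waist",
                 model@wallSpacing, model@waistRadius))
  L <- model@poreLength
  sp <- model@wallSpacing
  zs <- seq(-L / 2, L / 2, by = sp)
  rows <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    z <- zs[i]
    a <- modelRadius(model, z) + model@wallVdw
    m <- max(8L, as.integer(ceiling(2 * pi * a / sp)))
    th <- 2 * pi * (seq_len(m) - 1) / m + (i %% 2L) * pi / m
    rows[[i]] <- data.frame(x = a * cos(th), y = a * sin(th), z = z)
  }
  xyz <- do.call(rbind, rows)
  atoms <- data.frame(id = seq_len(nrow(xyz)), name = "WAL",
                      element = "X", x = xyz$x, y = xyz$y, z = xyz$z,
                      radius = model@wallVdw)
  new("PoreStructure", atoms = atoms,
      metadata = list(source = "buildWall", seed = model@seed,
                      spacing = sp, vdw = model@wallVdw))
}

# Sample one frame's radial placement uniformly over the local disc.
.radialPlace <- function(Rloc) {
  r <- Rloc * sqrt(runif(length(Rloc)))
  th <- runif(length(Rloc), 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Simulate equilibrium water frames in the synthetic pore
#'
#' Draws each frame independently from the equilibrium distribution: pore
#' waters form an inhomogeneous Poisson process along s with intensity
#' \eqn{\lambda(s) = n_{bulk}\,\pi R(s)^2\, e^{-U(s)}} (U in kBT), placed
#' uniformly over the local cross-section. Independent frames make the
#' output exactly testable against Poisson/Boltzmann theory; molecule ids
#' are per-frame labels only (no dynamics). The ground truth (U on a fine
#' grid, the intensity, per-frame counts, the seed) is stored in the
#' trajectory metadata.
#'
#' @param model a \linkS4class{SyntheticPoreModel}.
#' @param nFrames number of frames (>= 1).
#' @param frameDt frame interval in ns (default 0.01).
#' @param seed integer seed (default: the model seed).
#' @return a \linkS4class{Trajectory} with \code{persistentIds = FALSE}.
#' @export
simulateEquilibrium <- function(model, nFrames, frameDt = 0.01,
                                seed = model@seed) {
  stopifnot(is(model, "SyntheticPoreModel"), nFrames >= 1)
  L <- model@poreLength
  ds <- 0.01
  sg <- seq(-L / 2 + ds / 2, L / 2 - ds / 2, by = ds)   # cell centers in s
  Rg <- modelRadius(model, -sg)
  u <- model@U(sg)
  if (any(!is.finite(exp(-u))) || any(exp(-u) < 0))
    stop("U(s) yields a negative or non-finite Boltzmann intensity")
  lam <- model@nBulk * pi * Rg^2 * exp(-u)
  cellMass <- lam * ds
  M <- sum(cellMass)
  times <- (seq_len(nFrames) - 1) * frameDt

  withr::with_seed(as.integer(seed), {
    counts <- rpois(nFrames, M)
    tot <- sum(counts)
    cells <- sample.int(length(sg), tot, replace = TRUE, prob = cellMass)
    sPos <- sg[cells] + runif(tot, -ds / 2, ds / 2)
    xy <- .radialPlace(modelRadius(model, -sPos))
    frameIdx <- rep(seq_len(nFrames) - 1L, counts)
    molId <- sequence(counts)
    coords <- data.frame(frame = frameIdx, time = times[frameIdx + 1L],
                         molId = molId, x = xy[, "x"], y = xy[, "y"],
                         z = -sPos)
  })

  new("Trajectory", coords = coords, times = times, persistentIds = FALSE,
      metadata = list(groundTruth = list(
        mode = "equilibrium", sGrid = sg, U = u, lambda = lam,
        expectedCount = M, perFrameCounts = counts,
        seed = as.integer(seed), frameDt = frameDt)))
}

# --- wetting dynamics ------------------------------------------------------

# Metropolis step for a walker confined to [lo, hi] with a piecewise
# density: weight w1 below mid, w2 at/above mid.
.gateWalk <- function(s0, nSteps, lo, hi, mid, w1, w2, stepSd) {
  out <- numeric(nSteps)
  s <- s0
  eps <- 1e-3
  dens <- function(x) if (x < mid) w1 else w2
  for (i in seq_len(nSteps)) {
    prop <- s + rnorm(1, sd = stepSd)
    if (prop > lo + eps && prop < hi - eps &&
        runif(1) < dens(prop) / dens(s)) s <- prop
    out[i] <- s
  }
  out
}

# Biased initial placement within the gate.
.gateDraw <- function(n, lo, hi, mid, w1, w2) {
  pick1 <- runif(n) < w1 / (w1 + w2)
  lo1 <- lo + 0.02; hi1 <- mid - 0.02
  lo2 <- mid + 0.02; hi2 <- hi - 0.02
  ifelse(pick1, runif(n, lo1, hi1), runif(n, lo2, hi2))
}

#' Simulate two-state wetting/de-wetting dynamics with continuous tracks
#'
#' The gate alternates between wetted and de-wetted states following a
#' continuous-time Markov chain with rates \code{kWet} (dry to wet) and
#' \code{kDry} (wet to dry). Each wetted episode holds
#' \code{1 + Poisson(wetMeanOcc - 1)} waters with persistent ids that
#' enter through a gate boundary at the episode start, perform a
#' Metropolis random walk inside the gate (biased across the two
#' sub-cavities by \code{subcavityWeights}), and leave through a boundary
#' at the episode end. Boundary positions around each event are staged so
#' that linear interpolation between the adjacent frames recovers the
#' event time exactly; the full event log and state log are emitted as
#' ground truth in the trajectory metadata. Scripted trapped waters start
#' inside the gate at t = 0 and are released at \code{trappedRelease}.
#'
#' Episodes too short to contain a frame are merged into their neighbours
#' before any water is placed, so the logged ground truth always matches
#' the emitted trajectory. \code{frameDt} must resolve the kinetics:
#' the call errors when it is not below the mean dwell time of both
#' states.
#'
#' @param model a \linkS4class{SyntheticPoreModel}.
#' @param duration simulated time in ns.
#' @param frameDt frame interval in ns.
#' @param seed integer seed (default: the model seed).
#' @param initState initial gate state, "wet" or "dry".
#' @return a \linkS4class{Trajectory} with \code{persistentIds = TRUE};
#'   \code{groundTruth(traj)} holds \code{events} (molId, time, type,
#'   side in the s convention), \code{states} (state, start, end) and the
#'   generator parameters. Water coordinates are emitted in x, y, z with
#'   z = -s.
#' @export
simulateWettingDynamics <- function(model, duration, frameDt,
                                    seed = model@seed,
                                    initState = c("wet", "dry")) {
  stopifnot(is(model, "SyntheticPoreModel"), duration > 0, frameDt > 0)
  initState <- match.arg(initState)
  if (model@kWet > 0 && frameDt >= 1 / model@kWet)
    stop("frameDt must be below the mean dry dwell time 1/kWet (undersampling)")
  if (model@kDry > 0 && frameDt >= 1 / model@kDry)
    stop("frameDt must be below the mean wet dwell time 1/kDry (undersampling)")

  gi <- model@gateInterval
  lo <- gi[1]; hi <- gi[2]; mid <- mean(gi)
  w1 <- model@subcavityWeights[1]; w2 <- model@subcavityWeights[2]
  stepSd <- sqrt(2 * model@walkDiffusion * frameDt)
  ft <- seq(0, duration, by = frameDt)
  nFr <- length(ft)
  graceFrames <- 5L

  withr::with_seed(as.integer(seed), {
    # 1. realize the telegraph process
    eps <- list(); t <- 0; st <- initState
    while (t < duration) {
      rate <- if (st == "wet") model@kDry else model@kWet
      dwell <- if (rate > 0) rexp(1, rate) else Inf
      en <- min(t + dwell, duration)
      eps[[length(eps) + 1L]] <- list(state = st, start = t, end = en)
      t <- en
      st <- if (st == "wet") "dry" else "wet"
    }
    # 2. merge episodes that contain no frame into their predecessor
    merged <- list()
    for (e in eps) {
      keepable <- any(ft >= e$start & ft < e$end) ||
        (e$end >= duration - 1e-12 && any(ft >= e$start - 1e-12))
      if (!length(merged)) { merged[[1]] <- e; next }
      lastIdx <- length(merged)
      if (!keepable) {                      # absorb into previous episode
        merged[[lastIdx]]$end <- e$end
      } else if (merged[[lastIdx]]$state == e$state) {
        merged[[lastIdx]]$end <- e$end      # same state after an absorb
      } else {
        merged[[lastIdx + 1L]] <- e
      }
    }
    states <- do.call(rbind, lapply(merged, function(e)
      data.frame(state = e$state, start = e$start, end = e$end)))

    nextId <- 0L
    waterRows <- list()
    events <- list()

    stage <- function(id, tEvent, type, side, sAdj, fIn, fOut) {
      # place the outside-frame position so the linear crossing is exact
      bound <- if (side > 0) hi else lo
      if (type == "entry") {
        alpha <- (tEvent - ft[fOut]) / frameDt    # fOut = frame before entry
        sPrev <- (bound - alpha * sAdj) / (1 - alpha)
        list(sOut = sPrev)
      } else {
        beta <- (tEvent - ft[fIn]) / frameDt      # fIn = last inside frame
        list(sOut = sAdj + (bound - sAdj) / beta)
      }
    }

    emitWater <- function(entryTime, exitTime, sideIn, sideOut, scripted = FALSE,
                          sStart = NULL) {
      nextId <<- nextId + 1L
      id <- nextId
      hasEntry <- !is.null(entryTime) && entryTime > 0
      # an exit is observable only if a frame follows it
      hasExit <- !is.null(exitTime) && is.finite(exitTime) &&
        exitTime < ft[nFr]
      f0 <- if (hasEntry) which(ft >= entryTime)[1] else 1L
      fL <- if (hasExit) max(which(ft < exitTime)) else nFr
      if (is.na(f0) || f0 > nFr || fL < f0) return(invisible(NULL))
      nIn <- fL - f0 + 1L
      s0 <- if (!is.null(sStart)) sStart else .gateDraw(1, lo, hi, mid, w1, w2)
      sIn <- c(s0, if (nIn > 1L) .gateWalk(s0, nIn - 1L, lo, hi, mid, w1, w2,
                                           stepSd))
      frames <- f0:fL
      sSer <- sIn
      if (hasEntry) {
        stg <- stage(id, entryTime, "entry", sideIn, sIn[1], f0, f0 - 1L)
        frames <- c(f0 - 1L, frames)
        sSer <- c(stg$sOut, sSer)
        events[[length(events) + 1L]] <<- data.frame(
          molId = id, time = entryTime, type = "entry", side = sideIn)
      }
      if (hasExit) {
        stg <- stage(id, exitTime, "exit", sideOut, sIn[nIn], fL, fL + 1L)
        bound <- if (sideOut > 0) hi else lo
        drift <- sign(sideOut) * 0.15 * seq_len(graceFrames)
        post <- pmin(fL + 1L + 0:(graceFrames - 1L), nFr)
        post <- post[!duplicated(post)]
        sPost <- stg$sOut + c(0, drift)[seq_along(post)]
        frames <- c(frames, post)
        sSer <- c(sSer, sPost)
        events[[length(events) + 1L]] <<- data.frame(
          molId = id, time = exitTime, type = "exit", side = sideOut)
      }
      waterRows[[length(waterRows) + 1L]] <<- data.frame(
        frame = frames - 1L, time = ft[frames], molId = id, s = sSer)
      invisible(NULL)
    }

    # 3. waters of each episode
    for (e in merged) {
      m <- if (e$state == "wet") model@wetMeanOcc else model@dryMeanOcc
      N <- if (e$state == "wet") 1L + rpois(1, max(m - 1, 0)) else rpois(1, m)
      if (N < 1L) next
      for (k in seq_len(N)) {
        sideIn <- sample(c(-1, 1), 1)
        sideOut <- sample(c(-1, 1), 1)
        emitWater(entryTime = if (e$start > 0) e$start else NULL,
                  exitTime = if (e$end < duration) e$end else Inf,
                  sideIn = sideIn, sideOut = sideOut)
      }
    }

    # 4. scripted trapped waters
    if (model@trappedN > 0L) {
      rel <- model@trappedRelease
      length(rel) <- model@trappedN
      for (k in seq_len(model@trappedN)) {
        emitWater(entryTime = NULL,
                  exitTime = if (!is.na(rel[k])) rel[k] else Inf,
                  sideIn = 1, sideOut = sample(c(-1, 1), 1),
                  scripted = TRUE)
      }
    }

    coords <- if (length(waterRows)) do.call(rbind, waterRows) else
      data.frame(frame = integer(0), time = numeric(0), molId = integer(0),
                 s = numeric(0))
    xy <- if (nrow(coords)) {
      th <- 2 * pi * ((coords$molId * 0.6180339887) %% 1)
      r <- 0.05
      cbind(x = r * cos(th), y = r * sin(th))
    } else cbind(x = numeric(0), y = numeric(0))
    coords <- data.frame(frame = coords$frame, time = coords$time,
                         molId = coords$molId, x = xy[, "x"], y = xy[, "y"],
                         z = -coords$s)
    coords <- coords[order(coords$frame, coords$molId), , drop = FALSE]
    rownames(coords) <- NULL
    eventLog <- if (length(events)) {
      ev <- do.call(rbind, events)
      ev[order(ev$time, ev$molId), , drop = FALSE]
    } else data.frame(molId = integer(0), time = numeric(0),
                      type = character(0), side = numeric(0))
    rownames(eventLog) <- NULL
  })

  new("Trajectory", coords = coords, times = ft, persistentIds = TRUE,
      metadata = list(groundTruth = list(
        mode = "dynamics", events = eventLog, states = states,
        gateInterval = gi, seed = as.integer(seed), frameDt = frameDt,
        kWet = model@kWet, kDry = model@kDry)))
}
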