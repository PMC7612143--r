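#' PoreStructure: atoms defining a pore-forming structure
#'
#' Holds the atoms (pseudo-atoms or protein atoms) that line a channel-like
#' pore. Coordinates are in nm; each atom carries a van der Waals radius in
#' nm used by the probe-sphere pathway search.
#'
#' @slot atoms data.frame with columns \code{id}, \code{name},
#'   \code{element}, \code{x}, \code{y}, \code{z} (nm), \code{radius} (nm)
#'   and optionally \code{resid}/\code{resname} for reporting.
#' @slot metadata list of provenance information (source file, units).
#' @export
setClass("PoreStructure",
  representation(atoms = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("PoreStructure", function(object) {
  a <- object@atoms
  need <- c("id", "name", "element", "x", "y", "z", "radius")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 4L) return("a PoreStructure needs at least 4 atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("atom positions must be finite")
  if (!all(is.finite(a$radius)) || any(a$radius <= 0))
    return("all van der Waals radii must be finite and > 0")
  TRUE
})

#' Pathway: pore centerline with arc-length coordinate and radius profile
#'
#' An ordered polyline through the pore lumen. \code{s} is the arc-length
#' coordinate in nm with s = 0 at a gate reference point (by default the
#' narrowest point); s increases toward the intracellular side so that for
#' an axis-aligned pore z = -s up to a constant. \code{radius} is the local
#' probe (inscribed-sphere) radius in nm.
#'
#' @slot points numeric matrix (n x 3) of centerline coordinates in nm.
#' @slot s numeric, strictly increasing arc-length coordinate (nm).
#' @slot radius numeric, local pore radius (nm), one per point.
#' @slot axis numeric length-3 unit vector: the pore axis in the input
#'   frame, pointing in the direction of decreasing s (the +z sense of the
#'   z = -s convention).
#' @slot step numeric, slice advance used during construction (nm).
#' @slot metadata list (seed point, rng seed, stop criterion, convention).
#' @export
setClass("Pathway",
  representation(points = "matrix", s = "numeric", radius = "numeric",
                 axis = "numeric", step = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("Pathway", function(object) {
  n <- nrow(object@points)
  if (n < 2L) return("a Pathway needs at least 2 points")
  if (length(object@s) != n || length(object@radius) != n)
    return("s and radius must have one value per centerline point")
  if (any(diff(object@s) <= 0)) return("s must be strictly increasing")
  if (any(object@radius < 0)) return("radius must be >= 0 everywhere")
  seg <- sqrt(rowSums(diff(object@points)^2))
  if (any(seg > 2 * object@step + 1e-9))
    return("consecutive centerline points must be closer than 2 * step")
  if (abs(sum(object@axis^2) - 1) > 1e-6)
    return("axis must be a unit vector")
  TRUE
})

#' Trajectory: water coordinates over time
#'
#' Long-format storage of water (oxygen) positions per frame, in nm, with
#' times in ns. Molecule ids may be persistent across frames (required for
#' per-water tracking) or per-frame labels only (equilibrium snapshots).
#'
#' @slot coords data.frame with columns \code{frame} (integer index),
#'   \code{time} (ns), \code{molId}, \code{x}, \code{y}, \code{z} (nm).
#' @slot times numeric, strictly increasing frame times in ns (includes
#'   frames that contain no waters).
#' @slot persistentIds logical: TRUE if molIds identify the same molecule
#'   across frames.
#' @slot metadata list; synthetic trajectories store their ground truth
#'   (potential, event log, generator parameters, seed) here.
#' @export
setClass("Trajectory",
  representation(coords = "data.frame", times = "numeric",
                 persistentIds = "logical", metadata = "list"),
  prototype(persistentIds = FALSE, metadata = list()))

setValidity("Trajectory", function(object) {
  need <- c("frame", "time", "molId", "x", "y", "z")
  if (!all(need %in% names(object@coords)))
    return(paste("coords must have columns:", paste(need, collapse = ", ")))
  if (length(object@times) < 1L) return("at least one frame is required")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (nrow(object@coords) &&
      !all(is.finite(as.matrix(object@coords[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  TRUE
})

#' DensityProfile: time-averaged water number density along the pathway
#'
#' Local water number density n(s) in nm^-3 on a regular s grid, obtained
#' from a Gaussian KDE of pathway-mapped water positions (linear density
#' lambda(s) in nm^-1) divided by the local cross-section pi R(s)^2.
#'
#' @slot sGrid numeric, regular s grid (nm).
#' @slot density numeric, n(s) in nm^-3 (mean over frames/repeats).
#' @slot sd numeric, pointwise standard deviation of n(s).
#' @slot sdType character, "frames" or "repeats".
#' @slot lambda numeric, mean linear density (nm^-1).
#' @slot radiusGrid numeric, R(s) on the grid (nm).
#' @slot bandwidth numeric, KDE bandwidth (nm).
#' @slot nFrames integer, frames entering the average (summed over repeats).
#' @slot meanCount numeric, mean pore-water count per frame.
#' @slot repeatDensity matrix, one row of n(s) per repeat.
#' @slot missing logical, grid points where R(s) = 0 made density undefined.
#' @slot metadata list (equilibration cut, integral checks, repeat counts).
#' @export
setClass("DensityProfile",
  representation(sGrid = "numeric", density = "numeric", sd = "numeric",
                 sdType = "character", lambda = "numeric",
                 radiusGrid = "numeric", bandwidth = "numeric",
                 nFrames = "integer", meanCount = "numeric",
                 repeatDensity = "matrix", missing = "logical",
                 metadata = "list"),
  prototype(sdType = "frames", metadata = list()))

setValidity("DensityProfile", function(object) {
  n <- length(object@sGrid)
  if (n < 2L) return("grid needs at least 2 points")
  dg <- diff(object@sGrid)
  if (max(abs(dg - dg[1])) > 1e-8) return("s grid must be regular")
  if (length(object@density) != n) return("density must match grid length")
  ok <- !object@missing
  if (any(object@density[ok] < 0, na.rm = TRUE)) return("density must be >= 0")
  if (any(object@sd[ok] < 0, na.rm = TRUE)) return("sd must be >= 0")
  if (object@bandwidth <= 0) return("bandwidth must be > 0")
  TRUE
})

#' FreeEnergyProfile: free energy of wetting along the pathway
#'
#' G(s) in kBT units from Boltzmann inversion of a density profile,
#' normalized so that G averages to zero over the bulk-reference interval.
#' Zero-density points are set to a declared cap value and flagged.
#'
#' @slot sGrid numeric, s grid (nm).
#' @slot G numeric, free energy (kBT).
#' @slot sd numeric, pointwise SD (kBT) propagated from the density SD.
#' @slot capped logical, points where zero density was capped.
#' @slot temperature numeric (K).
#' @slot normConst numeric: the bulk reference density n_bulk (nm^-3); the
#'   additive constant is kBT*ln(normConst).
#' @slot bulkInterval numeric length-2, s range used as bulk reference.
#' @slot cap numeric, cap applied at zero density (kBT).
#' @slot repeatG matrix, per-repeat G(s) (each normalized by its own bulk).
#' @slot metadata list.
#' @export
setClass("FreeEnergyProfile",
  representation(sGrid = "numeric", G = "numeric", sd = "numeric",
                 capped = "logical", temperature = "numeric",
                 normConst = "numeric", bulkInterval = "numeric",
                 cap = "numeric", repeatG = "matrix", metadata = "list"),
  prototype(metadata = list()))

setValidity("FreeEnergyProfile", function(object) {
  if (object@temperature <= 0) return("temperature must be > 0")
  if (length(object@G) != length(object@sGrid))
    return("G must match grid length")
  bad <- !is.finite(object@G) & !object@capped
  if (any(bad)) return("G must be finite or flagged as capped")
  inBulk <- if (!is.null(object@metadata$bulkMask))
    object@metadata$bulkMask
  else
    object@sGrid >= object@bulkInterval[1] &
      object@sGrid <= object@bulkInterval[2]
  if (any(inBulk) && !any(object@capped[inBulk] | is.na(object@G[inBulk]))) {
    if (abs(mean(object@G[inBulk])) > 1e-6)
      return("G must average to 0 over the bulk-reference interval")
  }
  TRUE
})

#' StabilizationEstimate: Boltzmann stabilization of nanoconfined water
#'
#' The closed-form estimate dU = -RT ln(rhoP / mean(rhoNP)) in kJ/mol,
#' comparing the cavity water density under a polarizable model (rhoP)
#' with pooled fixed-charge densities (rhoNP).
#'
#' @slot rhoP numeric, polarizable-model cavity density (nm^-3).
#' @slot rhoNP numeric, fixed-charge cavity densities (nm^-3).
#' @slot pooled numeric, arithmetic mean of rhoNP.
#' @slot temperature numeric (K).
#' @slot deltaU numeric, stabilization energy (kJ/mol); -Inf when the
#'   pooled fixed-charge density is zero.
#' @slot degenerate logical, TRUE when pooled density was zero.
#' @export
setClass("StabilizationEstimate",
  representation(rhoP = "numeric", rhoNP = "numeric", pooled = "numeric",
                 temperature = "numeric", deltaU = "numeric",
                 degenerate = "logical"))

setValidity("StabilizationEstimate", function(object) {
  if (object@rhoP <= 0) return("rhoP must be > 0")
  if (object@pooled < 0) return("pooled density must be >= 0")
  if (!object@degenerate) {
    wantNeg <- object@rhoP >= object@pooled
    if (wantNeg != (object@deltaU <= 0 + 1e-12))
      return("deltaU must be <= 0 iff rhoP >= pooled rhoNP")
  }
  TRUE
})

#' WaterTrack: one water molecule's path through a tracked region
#'
#' Time series of the pathway coordinate for one molecule while inside the
#' tracked s interval, plus entry/exit events with boundary-crossing times
#' obtained by linear interpolation between frames.
#'
#' @slot molId integer molecule id.
#' @slot time numeric, frame times (ns) while inside the region.
#' @slot s numeric, pathway coordinate at those times (nm); note z = -s.
#' @slot events data.frame with columns \code{time} (ns), \code{type}
#'   ("entry"/"exit") and \code{side} (+1 = upper-s boundary, -1 = lower).
#' @slot region numeric length-2, the tracked s interval.
#' @export
setClass("WaterTrack",
  representation(molId = "integer", time = "numeric", s = "numeric",
                 events = "data.frame", region = "numeric"))

setValidity("WaterTrack", function(object) {
  if (length(object@time) && any(diff(object@time) <= 0))
    return("track times must be strictly increasing")
  ev <- object@events
  if (nrow(ev) > 1L) {
    if (any(diff(ev$time) < 0)) return("event times must be non-decreasing")
    if (any(ev$type[-1] == ev$type[-nrow(ev)]))
      return("events must alternate entry/exit")
  }
  TRUE
})

#' WettingSeries: per-frame gate occupancy and wetted/de-wetted states
#'
#' @slot time numeric, frame times (ns).
#' @slot occupancy numeric, pore-water count in the gate per frame.
#' @slot wetted logical, frame-wise state labels (occupancy >= threshold).
#' @slot threshold numeric, occupancy threshold defining "wetted".
#' @slot wettedFraction numeric in [0, 1].
#' @slot dwellWet numeric, dwell times (ns) of maximal wetted runs.
#' @slot dwellDry numeric, dwell times (ns) of maximal de-wetted runs.
#' @slot metadata list.
#' @export
setClass("WettingSeries",
  representation(time = "numeric", occupancy = "numeric", wetted = "logical",
                 threshold = "numeric", wettedFraction = "numeric",
                 dwellWet = "numeric", dwellDry = "numeric",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("WettingSeries", function(object) {
  if (object@threshold < 1) return("threshold must be >= 1")
  if (object@wettedFraction < 0 || object@wettedFraction > 1)
    return("wetted fraction must lie in [0, 1]")
  if (!identical(object@wetted, object@occupancy >= object@threshold))
    return("state labels must be consistent with the threshold")
  n <- length(object@time)
  if (n > 1L) {
    dt <- object@time[2] - object@time[1]
    if (abs(sum(object@dwellWet) + sum(object@dwellDry) - n * dt) > 1e-6)
      return("dwell times must sum to the analysed duration")
  }
  TRUE
})

#' SyntheticPoreModel: ground-truth model behind the synthetic generator
#'
#' Defines an hourglass (or cylindrical) pore of known radius profile, an
#' external potential U(s) in kBT governing equilibrium water density, and
#' optional two-state wetting kinetics plus trapped-water episodes. All
#' randomness derives from \code{seed}.
#'
#' The default geometry mirrors a tight hydrophobic gate: waist radius
#' 0.16 nm over a 0.5 nm waist (a ~0.04 nm^3 nanocavity), opening to
#' 0.5 nm mouths over 1 nm ramps, total pore length 6 nm.
#'
#' @slot poreLength numeric, total length along z (nm).
#' @slot mouthRadius,waistRadius numeric, pore radii (nm).
#' @slot waistLength,rampLength numeric, waist extent and ramp length (nm).
#' @slot wallSpacing numeric, pseudo-atom spacing on the wall surface (nm).
#' @slot wallVdw numeric, pseudo-atom van der Waals radius (nm).
#' @slot U function of s (nm) returning the potential in kBT.
#' @slot nBulk numeric, bulk water number density (nm^-3).
#' @slot temperature numeric (K).
#' @slot kWet,kDry numeric, two-state transition rates (ns^-1):
#'   dry->wet and wet->dry respectively.
#' @slot wetMeanOcc numeric >= 1, mean gate occupancy in the wetted state
#'   (drawn as 1 + Poisson(mean - 1) so a wet episode holds >= 1 water).
#' @slot dryMeanOcc numeric >= 0, mean occupancy in the de-wetted state.
#' @slot gateInterval numeric length-2, gate region in s (nm).
#' @slot subcavityWeights numeric length-2, relative stationary occupancy
#'   weights of the lower-s and upper-s sub-cavities.
#' @slot walkDiffusion numeric, in-gate walker diffusion coefficient
#'   (nm^2/ns).
#' @slot trappedN integer, number of scripted trapped waters.
#' @slot trappedRelease numeric, release times (ns) for trapped waters
#'   (NA = never released).
#' @slot seed integer, generator seed.
#' @export
setClass("SyntheticPoreModel",
  representation(poreLength = "numeric", mouthRadius = "numeric",
                 waistRadius = "numeric", waistLength = "numeric",
                 rampLength = "numeric", wallSpacing = "numeric",
                 wallVdw = "numeric", U = "function", nBulk = "numeric",
                 temperature = "numeric", kWet = "numeric", kDry = "numeric",
                 wetMeanOcc = "numeric", dryMeanOcc = "numeric",
                 gateInterval = "numeric", subcavityWeights = "numeric",
                 walkDiffusion = "numeric", trappedN = "integer",
                 trappedRelease = "numeric", seed = "integer"))

setValidity("SyntheticPoreModel", function(object) {
  if (object@poreLength <= 0) return("poreLength must be > 0")
  if (object@mouthRadius <= 0 || object@waistRadius <= 0)
    return("radii must be > 0")
  if (object@waistRadius > object@mouthRadius)
    return("waistRadius must not exceed mouthRadius")
  if (object@wallSpacing <= 0) return("wallSpacing must be > 0")
  if (object@kWet < 0 || object@kDry < 0) return("rates must be >= 0")
  if (object@wetMeanOcc < 1) return("wetMeanOcc must be >= 1")
  if (object@dryMeanOcc < 0) return("dryMeanOcc must be >= 0")
  if (diff(object@gateInterval) <= 0)
    return("gateInterval must be increasing")
  if (length(object@subcavityWeights) != 2L ||
      any(object@subcavityWeights <= 0))
    return("subcavityWeights must be two positive numbers")
  if (object@nBulk <= 0) return("nBulk must be > 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  u <- object@U(seq(-object@poreLength / 2, object@poreLength / 2,
                    length.out = 11))
  if (!all(is.finite(u))) return("U must be finite over the pore")
  TRUE
})

#' RunConfig: validated configuration for the end-to-end pipeline
#'
#' @slot structureFile,trajectoryFile,pathwayFile character paths (NA for
#'   unused inputs; a pathway file replaces structure + pathway search).
#' @slot seedPoint numeric length-3, pathway search seed (nm).
#' @slot step,searchRadius numeric, pathway search parameters (nm).
#' @slot bandwidth numeric, KDE bandwidth (nm, default 0.14).
#' @slot gridSpacing numeric, profile grid spacing (nm).
#' @slot equilibrationCut numeric, ns discarded as equilibration
#'   (default 10).
#' @slot temperature numeric (K, default 310).
#' @slot radialCutoffFactor numeric, pore-water radial cutoff as a multiple
#'   of R(s).
#' @slot gateInterval numeric length-2, gate s interval (nm).
#' @slot bulkInterval numeric length-2 or NA for automatic (outermost
#'   0.5 nm of each pathway end).
#' @slot wettedThreshold numeric, occupancy threshold.
#' @slot pseudoRadiiFromB logical, read per-atom radii from the PDB
#'   B-factor column (pseudo-atom wall convention).
#' @slot seed integer.
#' @slot outDir character, output directory.
#' @export
setClass("RunConfig",
  representation(structureFile = "character", trajectoryFile = "character",
                 pathwayFile = "character", seedPoint = "numeric",
                 step = "numeric", searchRadius = "numeric",
                 bandwidth = "numeric", gridSpacing = "numeric",
                 equilibrationCut = "numeric", temperature = "numeric",
                 radialCutoffFactor = "numeric", gateInterval = "numeric",
                 bulkInterval = "numeric", wettedThreshold = "numeric",
                 pseudoRadiiFromB = "logical",
                 seed = "integer", outDir = "character"))

setValidity("RunConfig", function(object) {
  pos <- c(step = object@step, searchRadius = object@searchRadius,
           bandwidth = object@bandwidth, gridSpacing = object@gridSpacing,
           temperature = object@temperature,
           radialCutoffFactor = object@radialCutoffFactor,
           wettedThreshold = object@wettedThreshold)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return(paste("parameters must be positive:",
                 paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", ")))
  if (object@equilibrationCut < 0)
    return("equilibrationCut must be >= 0")
  if (diff(object@gateInterval) <= 0)
    return("gateInterval must be an increasing interval")
  if (!anyNA(object@bulkInterval) && diff(object@bulkInterval) <= 0)
    return("bulkInterval must be an increasing interval")
  TRUE
})
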