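#' @name accessors
#' @title Accessor generics for PoreHydration classes
#'
#' @description Small accessor generics so that user code never touches
#' slots directly: \code{sCoord} (s grid / arc-length coordinate),
#' \code{poreRadius} (radius profile), \code{densityValues},
#' \code{freeEnergy}, \code{profileSD}, \code{nFrames}, \code{molId},
#' \code{trackEvents}, \code{wettedFraction}, \code{dwellTimes} and
#' \code{groundTruth}.
#'
#' @param x an object of the documented classes.
#' @param ... further arguments for methods.
#' @return the requested component, as a base vector/matrix/data.frame.
NULL

#' @rdname accessors
#' @export
setGeneric("sCoord", function(x, ...) standardGeneric("sCoord"))
#' @rdname accessors
#' @export
setGeneric("poreRadius", function(x, ...) standardGeneric("poreRadius"))
#' @rdname accessors
#' @export
setGeneric("densityValues", function(x, ...) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x, ...) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setGeneric("profileSD", function(x, ...) standardGeneric("profileSD"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("molId", function(x, ...) standardGeneric("molId"))
#' @rdname accessors
#' @export
setGeneric("trackEvents", function(x, ...) standardGeneric("trackEvents"))
#' @rdname accessors
#' @export
setGeneric("wettedFraction", function(x, ...) standardGeneric("wettedFraction"))
#' @rdname accessors
#' @export
setGeneric("dwellTimes", function(x, state = c("wet", "dry"), ...)
  standardGeneric("dwellTimes"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("sCoord", "Pathway", function(x, ...) x@s)
#' @rdname accessors
#' @export
setMethod("sCoord", "DensityProfile", function(x, ...) x@sGrid)
#' @rdname accessors
#' @export
setMethod("sCoord", "FreeEnergyProfile", function(x, ...) x@sGrid)
#' @rdname accessors
#' @export
setMethod("sCoord", "WaterTrack", function(x, ...) x@s)

#' @rdname accessors
#' @export
setMethod("poreRadius", "Pathway", function(x, ...) x@radius)
#' @rdname accessors
#' @export
setMethod("poreRadius", "DensityProfile", function(x, ...) x@radiusGrid)

#' @rdname accessors
#' @export
setMethod("densityValues", "DensityProfile", function(x, ...) x@density)
#' @rdname accessors
#' @export
setMethod("freeEnergy", "FreeEnergyProfile", function(x, ...) x@G)

#' @rdname accessors
#' @export
setMethod("profileSD", "DensityProfile", function(x, ...) x@sd)
#' @rdname accessors
#' @export
setMethod("profileSD", "FreeEnergyProfile", function(x, ...) x@sd)

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x, ...) length(x@times))
#' @rdname accessors
#' @export
setMethod("nFrames", "DensityProfile", function(x, ...) x@nFrames)

#' @rdname accessors
#' @export
setMethod("molId", "WaterTrack", function(x, ...) x@molId)
#' @rdname accessors
#' @export
setMethod("trackEvents", "WaterTrack", function(x, ...) x@events)

#' @rdname accessors
#' @export
setMethod("wettedFraction", "WettingSeries", function(x, ...) x@wettedFraction)
#' @rdname accessors
#' @export
setMethod("dwellTimes", "WettingSeries", function(x, state = c("wet", "dry"), ...) {
  state <- match.arg(state)
  if (state == "wet") x@dwellWet else x@dwellDry
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "Trajectory", function(x, ...) x@metadata$groundTruth)

setMethod("show", "PoreStructure", function(object) {
  cat("PoreStructure with", nrow(object@atoms), "atoms\n")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  rng <- apply(xyz, 2, range)
  cat(sprintf("  extent (nm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  cat(sprintf("  vdW radii (nm): %.3f - %.3f\n",
              min(object@atoms$radius), max(object@atoms$radius)))
})

setMethod("show", "Pathway", function(object) {
  cat("Pathway with", nrow(object@points), "centerline points\n")
  cat(sprintf("  s range (nm): [%.2f, %.2f], step %.3f nm\n",
              min(object@s), max(object@s), object@step))
  i <- which.min(object@radius)
  cat(sprintf("  min radius %.3f nm at s = %.2f nm; convention z = -s\n",
              object@radius[i], object@s[i]))
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "frames,",
      sprintf("%.2f - %.2f ns;", min(object@times), max(object@times)),
      nrow(object@coords), "water records\n")
  cat("  persistent molecule ids:", object@persistentIds, "\n")
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf("DensityProfile on %d grid points (spacing %.3f nm)\n",
              length(object@sGrid), diff(object@sGrid[1:2])))
  cat(sprintf("  bandwidth %.3f nm, %d frames, %d repeat(s), SD over %s\n",
              object@bandwidth, object@nFrames, nrow(object@repeatDensity),
              object@sdType))
  cat(sprintf("  mean pore-water count/frame: %.2f; density range %.2f - %.2f nm^-3\n",
              object@meanCount, min(object@density, na.rm = TRUE),
              max(object@density, na.rm = TRUE)))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  cat(sprintf("FreeEnergyProfile (kBT) on %d grid points, T = %.0f K\n",
              length(object@sGrid), object@temperature))
  cat(sprintf("  bulk reference s in [%.2f, %.2f] nm (n_bulk = %.2f nm^-3)\n",
              object@bulkInterval[1], object@bulkInterval[2], object@normConst))
  cat(sprintf("  max G = %.2f kBT; %d capped point(s) at %.0f kBT\n",
              max(object@G, na.rm = TRUE), sum(object@capped), object@cap))
})

setMethod("show", "WettingSeries", function(object) {
  cat(sprintf("WettingSeries: %d frames, threshold %g water(s)\n",
              length(object@time), object@threshold))
  cat(sprintf("  wetted fraction %.3f; %d wet dwell(s), %d dry dwell(s)\n",
              object@wettedFraction, length(object@dwellWet),
              length(object@dwellDry)))
})

setMethod("show", "StabilizationEstimate", function(object) {
  cat(sprintf("Boltzmann stabilization at %.0f K: dU = %.3f kJ/mol\n",
              object@temperature, object@deltaU))
  cat(sprintf("  rhoP = %.1f nm^-3 vs pooled rhoNP = %.1f nm^-3 (mean of %s)\n",
              object@rhoP, object@pooled,
              paste(object@rhoNP, collapse = ", ")))
})

setMethod("show", "SyntheticPoreModel", function(object) {
  cat("SyntheticPoreModel\n")
  cat(sprintf("  pore length %.1f nm; mouth %.2f / waist %.2f nm (waist %.2f nm long)\n",
              object@poreLength, object@mouthRadius, object@waistRadius,
              object@waistLength))
  cat(sprintf("  n_bulk %.1f nm^-3, T %.0f K, kWet %.2f / kDry %.2f ns^-1, seed %d\n",
              object@nBulk, object@temperature, object@kWet, object@kDry,
              object@seed))
})

setMethod("show", "WaterTrack", function(object) {
  cat(sprintf("WaterTrack for molecule %d: %d in-region frames, %d event(s)\n",
              object@molId, length(object@time), nrow(object@events)))
})
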