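# Boltzmann inversion, barrier extraction and closed-form nanoconfinement
# energetics.

.bulkIndices <- function(grid, bulkInterval) {
  grid >= bulkInterval[1] & grid <= bulkInterval[2]
}

# Default bulk reference: the outermost 0.5 nm at each end of the grid,
# pooled. Returned as the index mask plus a nominal interval for metadata.
.defaultBulkMask <- function(grid, margin = 0.5) {
  grid <= min(grid) + margin | grid >= max(grid) - margin
}

#' Boltzmann-invert a density profile into a free-energy profile
#'
#' Computes \eqn{G(s) = -\ln(n(s)/\bar n_{bulk})} in kBT units, with
#' \eqn{\bar n_{bulk}} the mean density over the bulk-reference interval,
#' so that G averages to zero outside the pore. Grid points with zero
#' density (fully de-wetted) are set to the declared cap and flagged. The
#' pointwise SD is propagated by applying the same transform to the
#' density mean plus/minus its SD. Per-repeat profiles are inverted with
#' their own bulk normalization so that barrier spread across repeats can
#' be quoted.
#'
#' @param density a \linkS4class{DensityProfile}.
#' @param temperature temperature in K (default 310; G itself is in kBT
#'   units, the temperature is carried for kJ/mol conversions).
#' @param bulkInterval numeric length-2 s interval (nm) used as bulk
#'   reference, or NULL for the default (outermost 0.5 nm at each pathway
#'   end, pooled).
#' @param cap finite value (kBT) reported at zero-density points
#'   (default 25).
#' @return a \linkS4class{FreeEnergyProfile}.
#' @export
boltzmannInvert <- function(density, temperature = 310, bulkInterval = NULL,
                            cap = 25) {
  stopifnot(is(density, "DensityProfile"), temperature > 0, cap > 0)
  grid <- density@sGrid
  n <- density@density
  ok <- !density@missing & !is.na(n)
  if (any(n[ok] < 0)) stop("negative density: cannot Boltzmann-invert")

  if (is.null(bulkInterval)) {
    mask <- .defaultBulkMask(grid)
    bulkInterval <- range(grid)   # pooled ends; recorded nominally
  } else {
    if (bulkInterval[1] < min(grid) - 1e-9 || bulkInterval[2] > max(grid) + 1e-9)
      stop("bulkInterval must lie within the profile grid")
    mask <- .bulkIndices(grid, bulkInterval)
  }
  if (!any(mask & ok)) stop("no usable grid points in the bulk interval")
  nBulk <- mean(n[mask & ok])
  if (nBulk <= 0) stop("zero bulk density: cannot normalize the profile")

  invert <- function(v, nb) {
    g <- rep(NA_real_, length(v))
    zero <- !is.na(v) & v <= 0
    pos <- !is.na(v) & v > 0
    g[pos] <- -log(v[pos] / nb)
    g[zero] <- cap
    pmin(g, cap)
  }
  G <- invert(n, nBulk)
  capped <- !is.na(n) & (n <= 0 | G >= cap)
  # recentre exactly on the (non-capped) bulk points so G averages to zero
  adj <- mean(G[mask & ok & !capped])
  G[!capped & !is.na(G)] <- G[!capped & !is.na(G)] - adj
  nBulkEff <- nBulk * exp(-adj)

  lo <- invert(n + density@sd, nBulkEff)
  hi <- invert(pmax(n - density@sd, 0), nBulkEff)
  sdG <- (hi - lo) / 2
  sdG[capped] <- NA_real_

  reps <- density@repeatDensity
  repG <- matrix(NA_real_, nrow(reps), ncol(reps))
  for (i in seq_len(nrow(reps))) {
    nb <- mean(reps[i, mask & ok])
    if (is.finite(nb) && nb > 0) repG[i, ] <- invert(reps[i, ], nb)
  }

  new("FreeEnergyProfile", sGrid = grid, G = G, sd = sdG, capped = capped,
      temperature = temperature, normConst = nBulkEff,
      bulkInterval = bulkInterval, cap = cap, repeatG = repG,
      metadata = list(bulkMask = mask, sdType = density@sdType))
}

#' Extract the free-energy barrier over the gate region
#'
#' Returns the maximum of the repeat-mean G over the gate interval, and
#' the population standard deviation across repeats of each repeat's own
#' maximum (NA when only one repeat is available).
#'
#' @param G a \linkS4class{FreeEnergyProfile}.
#' @param gateInterval numeric length-2 s interval (nm).
#' @return list with elements \code{barrier} (kBT), \code{sd} (kBT),
#'   \code{sAtMax} (nm) and \code{perRepeat} (numeric vector).
#' @export
barrierHeight <- function(G, gateInterval) {
  stopifnot(is(G, "FreeEnergyProfile"), length(gateInterval) == 2)
  idx <- which(G@sGrid >= gateInterval[1] & G@sGrid <= gateInterval[2])
  if (!length(idx)) stop("empty gate interval: no grid points inside")
  g <- G@G[idx]
  if (all(is.na(g))) stop("free energy undefined over the whole gate interval")
  i <- idx[which.max(G@G[idx])]
  perRep <- apply(G@repeatG[, idx, drop = FALSE], 1,
                  function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  nRep <- sum(!is.na(perRep))
  sdv <- if (nRep > 1) {
    v <- perRep[!is.na(perRep)]
    sqrt(mean((v - mean(v))^2))
  } else NA_real_
  list(barrier = max(g, na.rm = TRUE), sd = sdv, sAtMax = G@sGrid[i],
       perRepeat = perRep)
}

#' Boltzmann stabilization energy of nanoconfined water
#'
#' Closed-form estimate \eqn{\Delta U = -RT\,\ln(\rho_P/\bar\rho_{NP})}
#' in kJ/mol, where \eqn{\rho_P} is the cavity water density under a
#' polarizable model and \eqn{\bar\rho_{NP}} the arithmetic mean of the
#' supplied fixed-charge densities. A negative value means the polarizable
#' model stabilizes water in the cavity.
#'
#' @param rhoP polarizable-model cavity density (nm^-3), > 0.
#' @param rhoNP numeric vector of fixed-charge densities (nm^-3), >= 0.
#' @param temperature temperature in K (default 310).
#' @return a \linkS4class{StabilizationEstimate}; when the pooled
#'   fixed-charge density is zero, \code{deltaU} is -Inf and the estimate
#'   is flagged degenerate.
#' @examples
#' stabilizationEnergy(35, c(22, 16), 310)  # ~ -1.6 kJ/mol
#' stabilizationEnergy(15, c(0, 6), 310)    # ~ -4.1 kJ/mol
#' @export
stabilizationEnergy <- function(rhoP, rhoNP, temperature = 310) {
  if (!is.numeric(rhoP) || length(rhoP) != 1L || rhoP <= 0)
    stop("rhoP must be a single value > 0")
  if (!is.numeric(rhoNP) || !length(rhoNP) || any(rhoNP < 0))
    stop("rhoNP must be a non-empty vector of values >= 0")
  stopifnot(temperature > 0)
  pooled <- mean(rhoNP)
  degenerate <- pooled <= 0
  dU <- if (degenerate) -Inf else -.RGAS * temperature * log(rhoP / pooled)
  new("StabilizationEstimate", rhoP = rhoP, rhoNP = rhoNP, pooled = pooled,
      temperature = temperature, deltaU = dU, degenerate = degenerate)
}

#' Water capacity of a cylindrical pore segment
#'
#' Number of water molecules that fit in a cylinder of the given radius
#' and length at one molecule per \code{molecularVolume}:
#' \eqn{\pi r^2 L / v}. Also returns the value rounded to the nearest ten
#' as a convenience for order-of-magnitude statements.
#'
#' @param radius cylinder radius (nm).
#' @param length cylinder length (nm).
#' @param molecularVolume volume per molecule (nm^3, default 0.03).
#' @return list with \code{count} and \code{rounded}.
#' @examples
#' cylinderCapacity(0.5, 2.0)  # ~52 waters, rounded 50
#' @export
cylinderCapacity <- function(radius, length, molecularVolume = 0.03) {
  stopifnot(radius > 0, length > 0, molecularVolume > 0)
  count <- pi * radius^2 * length / molecularVolume
  list(count = count, rounded = round(count / 10) * 10)
}

#' Volume occupied by one water molecule in bulk
#'
#' \eqn{M / (\rho N_A)}, expressed in nm^3. With the density of water near
#' physiological temperature this is about 0.03 nm^3, the reciprocal of
#' the ~33 nm^-3 bulk number density.
#'
#' @param density mass density in g/cm^3 (default 0.997).
#' @param molarMass molar mass in g/mol (default 18.015).
#' @return volume in nm^3.
#' @export
waterMolecularVolume <- function(density = 0.997, molarMass = 18.015) {
  stopifnot(density > 0, molarMass > 0)
  # g/mol / (g/cm^3 * 1/mol) = cm^3; 1 cm^3 = 1e21 nm^3
  molarMass / (density * .NAVO) * 1e21
}

#' Onsager reaction-field energy difference of a dipole in a cavity
#'
#' Potential energy of a point dipole at the center of a spherical cavity
#' embedded in a dielectric continuum,
#' \eqn{U(\epsilon) = -\frac{1}{4\pi\epsilon_0}\frac{\mu^2}{a^3}
#' \frac{\epsilon - 1}{2\epsilon + 1}}, evaluated as the difference
#' \eqn{U(\epsilon_b) - U(\epsilon_a)} in kJ/mol. Moving a water-sized
#' dipole from vacuum (eps 1) into a protein-like dielectric (eps 4)
#' stabilizes it by several kJ/mol.
#'
#' @param dipole dipole moment in debye.
#' @param cavityRadius cavity radius in nm.
#' @param epsOuterA,epsOuterB outer relative permittivities (>= 1).
#' @return energy difference in kJ/mol (negative = stabilized in B).
#' @examples
#' onsagerCavityEnergy(1.85, 0.193, 1, 4)  # about -9.6 kJ/mol
#' @export
onsagerCavityEnergy <- function(dipole, cavityRadius, epsOuterA = 1,
                                epsOuterB = 4) {
  stopifnot(dipole > 0, cavityRadius > 0)
  if (epsOuterA < 1 || epsOuterB < 1) stop("dielectric constants must be >= 1")
  mu <- dipole * .DEBYE               # C m
  a <- cavityRadius * 1e-9            # m
  U <- function(eps)
    -(1 / (4 * pi * .EPS0)) * mu^2 / a^3 * (eps - 1) / (2 * eps + 1)
  (U(epsOuterB) - U(epsOuterA)) * .NAVO / 1000
}
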