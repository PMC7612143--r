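---
title: "Pore hydration analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore hydration analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(PoreHydration)
```

## The problem

Narrow, apolar-lined segments of ion-channel pores can empty of water
spontaneously even though nothing physically occludes them. Such a
*hydrophobic gate* blocks ion permeation by a "vapour lock": the liquid
state of water inside the constriction is unstable, and the pore
stochastically switches between wetted and de-wetted states. Whether a
given constriction de-wets depends sensitively on its radius (down to
~0.15 nm, the size of one water molecule) and the hydrophobicity of its
lining. The standard computational readout is a trio of profiles along
the pore axis: the pore radius R(s), the time-averaged water number
density n(s), and the free energy of wetting G(s) obtained by Boltzmann
inversion of the density.

This package implements that readout as a self-contained pipeline:

1. **pathway** — probe-sphere search for the permeation pathway and R(s);
2. **hydration** — mapping water positions onto the pathway coordinate s
   and kernel density estimation of n(s);
3. **energetics** — Boltzmann inversion into G(s), gate barrier
   extraction, and closed-form nanoconfinement estimates;
4. **wetting dynamics** — per-water tracking (entries, exits, trapped
   waters, sub-cavity switching) and wetted/de-wetted state
   classification;
5. **synthetic data** — a seeded generator of pore walls and water
   trajectories with known ground truth, so that every stage is testable
   without molecular dynamics.

Internal units are nm and ns; energies are in kBT except where a
function explicitly returns kJ/mol; the default temperature is 310 K.

## Coordinate convention

The pathway coordinate s is the arc length along the pore centerline,
with s = 0 at the gate (the narrowest point, by default) and s
*increasing toward the intracellular side*. For a pore whose axis is
aligned with the membrane normal z this means z = −s up to a constant
offset: a water 1 nm above the gate centre in z sits at s = −1 nm. All
profiles, regions and tracks use s; `trackWaters(..., coordinate = "z")`
mirrors tracks into z for plotting against structure coordinates.

Placing s = 0 at the minimum-radius slice assumes the structure has a
genuine constriction. For a featureless cylinder the minimum is set by
optimizer noise and the origin is arbitrary; pass `sZero = "seed"` to
`findPathway()` in that case.

## Pathway finding

`findPathway()` re-implements the probe-sphere (HOLE/CHAP-style)
construction. The pore axis is estimated as the principal axis of the
atom cloud. Starting from a user seed inside the lumen, the search
advances in fixed steps (default 0.05 nm) along the axis; at each slice
the centerline point maximizes the inscribed-sphere radius

r(p) = min_i ( |p − x_i| − r_vdw,i )

over the plane perpendicular to the axis, by Nelder–Mead restarted from
the previous slice's centre. Restart jitters come from a fixed
low-discrepancy sequence keyed by `rngSeed`, so identical seeds give
bit-identical pathways without touching R's global RNG. The in-plane
optimization basis is anchored to the nearest atom, which makes the
whole construction equivariant under rigid rotations and translations of
the input to machine precision (the test suite asserts 1e-6 nm). The
pathway ends at the pore mouths, where R(s) exceeds 1.0 nm (configurable)
for three consecutive slices.

Van der Waals radii come from a bundled element table (H 0.12, C 0.17,
N 0.155, O 0.152, S 0.18 nm; carbon fallback); pseudo-atom walls carry
their radii in the PDB B-factor column (`pseudoRadiiFromB = TRUE`).
Per-slice lateral movement is capped at `searchRadius` (default 0.08 nm)
so consecutive centerline points always stay within twice the step; the
seed slice alone is searched over a wider 0.5 nm disc because the user's
seed may sit well off the true centerline.

The optimizer is validated against a brute-force oracle (a fine 2-D grid
scan of the same inscribed-radius function) and against closed-form
walls: for pseudo-atoms on an analytic surface of revolution the
recovered radius agrees with the construction within 0.02 nm, limited by
the wall's discrete atom spacing rather than by the optimizer.

## Density estimation

Waters are assigned to the pathway by nearest centerline point; the
coordinate is made continuous by adding the axial offset along the local
tangent (exact for straight centerlines). Waters whose radial distance
exceeds `radialCutoffFactor` × R(s) (default 1.2 — waters slightly
outside the probe radius still line the pore) are excluded as bulk/lipid
phase. Frames earlier than the equilibration cut (default 10 ns) are
discarded.

The per-frame s samples enter a Gaussian KDE with bandwidth 0.14 nm
(default), evaluated on a regular 0.02 nm grid and truncated at 4
bandwidths. Kernel mass is reflected at both grid ends: the pathway
opens into bulk where the density is locally flat, which reflection
represents exactly, and it makes the estimator conserve mass — the
integral of the linear density λ(s) equals the mean per-frame pore-water
count (asserted to 1 % in the tests). The local *number* density is

n(s) = λ(s) / (π R(s)²)  [nm⁻³],

i.e. the linear density divided by the local cross-section; with this
convention the profile approaches the bulk value (~33 nm⁻³) outside the
gate. Whether tools that report nm⁻³ profiles use the local
cross-section or a fixed reference volume is not standardized; the
choice here is asserted only for internal consistency (mass
conservation and bulk limit). The pointwise spread is the SD over
frames for a single run and the population SD over repeats after
`averageOverRepeats()`, matching the usual "± 1 SD over n repeats"
reporting with small n.

Because the KDE estimates the *kernel-smoothed* density, profile
features sharper than the bandwidth are attenuated: the estimator's
expectation is the convolution of the true λ with the kernel, and
recovery tests compare against that expectation (computed by independent
numerical convolution), plus a looser direct bound that allows for the
O(bandwidth²) smoothing bias. Smoothing bias is a resolution property of
the estimator, not Monte-Carlo error.

## Free energy and energetics

Boltzmann inversion uses

G(s) = −kBT ln n(s) + kBT ln C,

with C fixed so that G averages to zero over the bulk-reference
interval — by default the outermost 0.5 nm at each pathway end, pooled.
G is reported in kBT units. Zero-density grid points (fully de-wetted
throughout the analysis window) would be infinite; they are set to a
declared cap (default 25 kBT) and flagged so profiles remain plottable
and comparable. The SD is propagated by transforming density mean ± SD.
The gate barrier is the maximum of the repeat-mean G over the gate
interval, with the across-repeat SD of the per-repeat maxima as its
spread.

The closed-form estimates are deliberately simple:

* `stabilizationEnergy()` computes ΔU = −RT ln(ρP/ρ̄NP) in kJ/mol,
  pooling the fixed-charge densities by arithmetic mean. The pooling
  convention is this package's choice; it reproduces the published
  pairs of estimates to the printed precision.
* `cylinderCapacity()` is π r² L / v, with a rounded-to-ten convenience
  value for order-of-magnitude statements (a 0.5 nm × 2 nm gate holds
  ~50 waters; the 0.16 nm × 0.5 nm nanocavity holds ~1).
* `waterMolecularVolume()` gives M/(ρ N_A) ≈ 0.03 nm³, whose reciprocal
  is the bulk number density 33.3 nm⁻³ used throughout.
* `onsagerCavityEnergy()` evaluates the reaction-field energy
  U(ε) = −(1/4πε₀)(μ²/a³)(ε−1)/(2ε+1) of a point dipole centred in a
  spherical cavity, as a difference between two outer dielectrics. With
  a water dipole (1.85 D) in a cavity sized to one molecule (0.193 nm
  radius, i.e. a 0.03 nm³ sphere) and ε 1 → 4 it yields −9.6 kJ/mol.
  Literature figures of about −7 kJ/mol for the same physics rest on
  unstated parameter choices; this function targets the formula, not
  any particular printed value.

## Wetting dynamics

`classifyWetting()` labels a frame wetted when the gate holds at least
`threshold` waters. The default threshold is 1: the gates of interest
accommodate only ~1–4 waters, so a single molecule already constitutes
partial hydration. Dwell times are maximal-run durations; they sum to
the analysed duration by construction.

`trackWaters()` builds one track per molecule that ever enters the
region, with entry/exit events located by linear interpolation of the
boundary crossing between frames — frame intervals (≥ 10 ps) are coarse
relative to crossing events, and interpolation removes the frame-grid
quantization of event times. The exit side is the sign of the crossed
boundary in s. `trappedWaters()` flags tracks resident for ≥ 10 ns
(configurable) without an exit, the signature of waters caged between
two tight constrictions. `subcavityOccupancy()` splits the gate into two
sub-cavities (at the gate midpoint unless ring positions are supplied,
which is the honest default when only residue identities, not s-values,
are known) and reports per-frame counts, joint patterns such as (1,1)
versus (2,0), and the occupancy-time preference ratio.

## The synthetic generator

The generator emulates the *statistics* of water in a gated nanopore,
not its molecular mechanics — no water–water interactions, no membrane,
no polarizability. Two modes with cleanly separated test surfaces:

* **Equilibrium** (`simulateEquilibrium`): independent frames drawn from
  an inhomogeneous Poisson process along s with intensity
  λ(s) = n_bulk π R(s)² e^(−U(s)), placed uniformly over the local
  cross-section. Independence makes density and free-energy tests exact
  against Poisson/Boltzmann theory: the pipeline must recover U(s)
  within Monte-Carlo error. Molecule ids are per-frame labels only.
* **Dynamics** (`simulateWettingDynamics`): the gate follows a two-state
  continuous-time Markov chain (rates kWet, kDry); each wetted episode
  holds 1 + Poisson(mean − 1) waters — at least one, so that state
  classification at threshold 1 is identifiable — which enter through a
  gate boundary, perform a Metropolis random walk inside (biased across
  the two sub-cavities by the configured weights), and leave through a
  boundary at the episode end. Positions around each event are staged so
  that linear interpolation between the adjacent frames recovers the
  event time *exactly*; the emitted event log is therefore an exact
  oracle for the tracker. Episodes too short to contain any frame are
  merged before logging, so the log always matches the emitted frames.
  Scripted trapped waters start inside the gate and are released at set
  times. `frameDt` must be below the mean dwell time of both states
  (undersampling guard).

Default conditions: hourglass with a 0.16 nm waist over 0.5 nm (a
π·0.16²·0.5 ≈ 0.04 nm³ nanocavity, just above the 0.03 nm³ of one bulk
water), 0.5 nm mouths reached over 1 nm cosine ramps, 6 nm pore; bulk
density 33.3 nm⁻³; 310 K; wall pseudo-atoms of 0.15 nm vdW radius at
0.08 nm spacing. All randomness flows through one seed recorded in the
output metadata; identical seeds give identical trajectories and logs.

What passing tests on synthetic data do **not** show: force-field
realism, protein flexibility, finite water size and hydrogen bonding,
ion effects, or the actual kinetics of any real channel. They show that
the *analysis* is correct: given data whose ground truth is known, the
pipeline recovers it.

## Numerical choices

* KDE grid 0.02 nm, truncation 4 bandwidths, reflection at grid ends.
* Nelder–Mead with reltol 1e-12, up to 8 deterministic jittered restarts
  per slice, followed by a polish run; failure to find a positive
  inscribed radius names the slice in the error.
* Linear interpolation for `radiusProfile()` — shape-preserving, no
  overshoot at the waist.
* Zero-density cap 25 kBT, flagged per grid point.
* Population SD over repeats (not n−1), matching ±SD reporting at n ≤ 6.
* Physical constants centralized: R = 0.0083145 kJ mol⁻¹ K⁻¹,
  N_A = 6.02214e23 mol⁻¹, 1 D = 3.33564e-30 C·m, ε₀ = 8.8542e-12 F/m.
* Degenerate inputs: seeds with non-positive inscribed radius error;
  frames with zero waters are valid (they carry real information about
  de-wetting); an all-zero bulk interval errors; R(s) = 0 grid points
  are reported missing, not divided by.

## Worked example

A complete run on synthetic equilibrium data with a 2 kBT gate barrier:

```{r example, eval = FALSE}
U <- function(s) 2 * exp(-s^2 / (2 * 0.6^2))
mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.45,
                          waistLength = 0.5, rampLength = 1, U = U)
wall <- buildWall(mod)
pw <- findPathway(wall, c(0, 0, 0))
traj <- simulateEquilibrium(mod, nFrames = 2000, frameDt = 0.02, seed = 1)
dp <- densityProfile(mapToPathway(traj, pw), pw, equilibrationCut = 1)
fep <- boltzmannInvert(dp)
barrierHeight(fep, c(-1, 1))
plot(fep)
```

The recovered barrier lies within Monte-Carlo error (plus the documented
O(bandwidth²) smoothing bias) of the generating 2 kBT.

Typical problem sizes used by the package's own validation: 5000
equilibrium frames for free-energy recovery, 500 ns of telegraph
dynamics at 0.01 ns frames for dwell-time recovery — both chosen to make
3-SE Monte-Carlo assertions sharp at desk scale.

## Known limitations

* One branch: no side tunnels or bifurcated pathways, no cavity
  detection away from the seeded channel.
* The centerline axis is estimated globally (principal axis) and slices
  stay perpendicular to it; strongly curved pores would need a locally
  updated axis.
* Water only: no ion densities, no hydrophobicity surface profiling,
  no hydrogen-bond statistics.
* XTC trajectories are not read directly; binary trajectories must be
  converted to the documented CSV dialect first.
* The nm⁻³ conversion assumes the π R(s)² cross-section; comparisons
  with tools using a different reference volume need rescaling.
```
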