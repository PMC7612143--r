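# PoreHydration

Hydration analysis of channel-like nanopores: pore radius profiling,
water density and free-energy-of-wetting profiles, and wetting/de-wetting
dynamics of individual water molecules.

## The scientific problem

Narrow, hydrophobically lined segments of ion-channel pores can empty of
water spontaneously — a *hydrophobic gate* — closing the channel to ions
without any steric occlusion. The standard computational characterization
of such a gate is a trio of profiles along the pore-axis coordinate *s*:

- the pore radius **R(s)** from a probe-sphere (HOLE/CHAP-style) pathway
  search, `r(p) = min_i(|p − x_i| − r_vdw,i)` maximized over each slice;
- the time-averaged water number density **n(s)** (nm⁻³), from a Gaussian
  kernel density estimate of pathway-mapped water positions (default
  bandwidth 0.14 nm, 10 ns equilibration discard), converted with the
  local cross-section: n(s) = λ(s)/(πR(s)²);
- the free energy of wetting **G(s) = −k_BT ln n(s) + k_BT ln C**, with C
  chosen so G = 0 outside the pore; the gate barrier is the maximum of G
  over the gate region.

The package also quantifies the dynamics — per-frame wetted/de-wetted
classification, dwell times, per-water tracking with interpolated
entry/exit events, trapped-water detection, sub-cavity occupancy — and
closed-form nanoconfinement energetics: the Boltzmann stabilization
ΔU = −RT ln(ρ_P/ρ̄_NP) between polarizable and fixed-charge cavity
densities, cylinder water capacities, the bulk molecular volume of
water, and the Onsager reaction-field energy of a dipole in a cavity.

It is aimed at people analysing simulations (or building synthetic
models) of ion channels and biomimetic nanopores. No MD engine is
required: a seeded synthetic generator produces pore walls and water
trajectories with known ground truth (equilibrium Boltzmann statistics,
or two-state telegraph wetting kinetics with an exact event log), so the
entire pipeline is testable at desk scale. Everything uses nm/ns units;
the pathway convention is z = −s.

## Worked example

Build a synthetic hourglass pore with a 2 k_BT gate barrier, find its
pathway, and recover the barrier from equilibrium frames:

```r
library(PoreHydration)

U <- function(s) 2 * exp(-s^2 / (2 * 0.6^2))        # gate barrier, kBT
mod <- syntheticPoreModel(mouthRadius = 0.5, waistRadius = 0.45,
                          waistLength = 0.5, rampLength = 1, U = U)
wall <- buildWall(mod)
pw   <- findPathway(wall, c(0, 0, 0))
pw
#> Pathway with 121 centerline points
#>   s range (nm): [-2.80, 3.20], step 0.050 nm
#>   min radius 0.450 nm at s = 0.00 nm; convention z = -s

traj <- simulateEquilibrium(mod, nFrames = 2000, frameDt = 0.02, seed = 1)
dp   <- densityProfile(mapToPathway(traj, pw), pw, equilibrationCut = 1)
fep  <- boltzmannInvert(dp)
fep
#> FreeEnergyProfile (kBT) on 301 grid points, T = 310 K
#>   bulk reference s in [-2.80, 3.20] nm (n_bulk = 33.07 nm^-3)
#>   max G = 1.94 kBT; 0 capped point(s) at 25 kBT

b <- barrierHeight(fep, c(-1, 1))
# barrier 1.94 kBT at s = 0.20 nm (5.0 kJ/mol at 310 K)
```

The recovered 1.94 k_BT barrier agrees with the generating 2 k_BT within
Monte-Carlo error plus the documented O(bandwidth²) smoothing bias. The
closed-form estimates print directly:

```r
stabilizationEnergy(15, c(0, 6), 310)
#> Boltzmann stabilization at 310 K: dU = -4.148 kJ/mol
#>   rhoP = 15.0 nm^-3 vs pooled rhoNP = 3.0 nm^-3 (mean of 0, 6)
cylinderCapacity(0.5, 2.0)$rounded    # ~50 waters in a 1 nm x 2 nm gate
waterMolecularVolume()                # 0.030 nm^3 per bulk water
```

`runPipeline(runConfig(...))` chains pathway → density → energy →
wetting on files (PDB/GRO structures, a documented CSV trajectory
dialect, YAML configs) and writes per-stage CSV/JSON outputs plus a
provenance manifest. `inst/scripts/porehyd.R` exposes the same stages as
a command line (`pathway`, `density`, `energy`, `stabilize`, `track`,
`simulate`, `run`).

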