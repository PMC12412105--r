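---
title: "Models and methods behind capsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

capsort is a simulation suite for adhesion-based, label-free cell sorting on
microstructured thermoresponsive coatings. Such a coating consists of
cell-adhesive polymer domains (PGMA) embedded in a thermoresponsive
PNIPAM-co-GMA matrix: above the LCST (~32 °C) the matrix is collapsed and
cells adhere to the domains; cooling below the LCST swells the matrix, which
pushes weakly bound cells off while strongly bound ones remain. Sorting
works when the push-off force lies between the adhesion strengths of the two
cell types. The package implements the three computational layers of this
problem — surface characterization, film physics, and cell-scale sorting —
as one tested toolchain:

1. **capgeom / heightmap** — spherical-cap geometry of the domains, summary
   statistics of cap-decorated surfaces, and a synthetic SPM height-map
   generator/analyzer used as a download-free test bed.
2. **dpd_film** — a dissipative particle dynamics engine for the grafted,
   cross-linkable matrix: phase separation, stochastic cross-linking, and
   LCST-switchable swelling.
3. **mc_cellsort** — a Metropolis Monte Carlo model of two cell types
   adsorbing to and detaching from the micropatterned surface.

This vignette records the models, the parameter choices (including all
choices that were genuinely open), and the limitations.

## Spherical-cap geometry and surface statistics

Phase-separated domains are modeled as spherical caps: sphere radius
`R_sp`, height `H` above the basal plane, base radius
`R_d' = sqrt(H (2 R_sp − H))`, and slice radius
`r(h) = sqrt(R_sp² − (R_sp − H + h)²)` for a horizontal cut at height `h`.
All heights are background-subtracted: the basal plane is set to zero after
removing the basal roughness level, which is the convention used in
structural tables of such surfaces. The monotone decrease of `r(h)` with
`h` holds for sub-hemispherical caps (`H ≤ R_sp`); fabricated domains are
far below the hemisphere, but the functions accept any valid cap and the
slice radius correctly widens toward the equator above it.

`surface_stats()` reports medians and interquartile ranges rather than
means and standard deviations because measured cap-height distributions are
broad and right-skewed. The neighbour distance `d` is the per-domain mean
distance to its 4 nearest neighbours, averaged over domains; domains whose
4-NN ball would cross the field border are excluded (a finite scan cannot
see neighbours outside it), and no periodic wrapping is applied. The
coverage column is the product `ρ × median(A)` of the module's own density
and exposed-area statistics; published tables of this kind print a coverage
that is not exactly the product of their printed columns (most likely a
different estimator over the raw per-domain data), and we deliberately do
not guess that estimator.

The unit map calibrates reduced simulation lengths to nanometres by
matching cap heights and base radii separately. The two factors genuinely
differ (lateral factor ≈ 4× the height factor in the system this package
models): simulated domains sit less immersed in the substrate than
fabricated ones, so one isotropic factor cannot match both.

## Synthetic height maps

`generate_heightmap()` emulates an SPM scan: caps are placed by random
sequential adsorption without base-disk overlap in a finite, non-periodic
field; per-pixel height is the maximum of basal roughness, matrix level and
cap surfaces. Cap heights and sphere radii are lognormal, parameterized by
median and IQR — positive, right-skewed, and matching how the real
distributions are summarized. The basal roughness amplitude `h_bg`
(typically 3–7 nm) is implemented as truncated Gaussian per-pixel noise
with mean `h_bg/2` and SD `h_bg/4`, giving a typical peak-to-valley scale
of `h_bg`; only an amplitude range is known for real surfaces, so a noise
*model* had to be chosen, and independent Gaussian pixels are the simplest
defensible one (no lateral correlation — see Limitations).

`analyze_heightmap()` mirrors the slicing procedure used for real scans:
background = 10th percentile of heights (robust while domains cover less
than roughly half the area), 8-connected component labeling above a
detection threshold (8- rather than 4-connectivity because caps are convex
blobs and 4-connectivity splits them at diagonal pixel steps), border
domains excluded, per-domain maximum height, per-slice equivalent-disc
radii `R_d(h) = sqrt(area/π)`, and `R_sp` by least squares on the cap
relation across slices (the relation is linear in `R_sp` given `H`, so the
fit is closed-form). Five slice levels between the threshold and 90% of
each domain's maximum height are used by default; the number is not
critical because the per-slice single-slice inversions agree within a few
percent for cap-shaped domains, which is itself a reported diagnostic
(`Rsp_spread`).

When a matrix covers the basal plane, the analyzer's zero is the matrix
surface, not the buried basal plane; recovered heights are matrix-relative.
Matrix-free surfaces (emulating domain-only samples) are the round-trip
test bed for absolute `H` and `R_sp` recovery.

## The DPD film engine

Standard DPD: soft conservative force `a_ij (1 − r/r_c)`, pairwise
dissipative and random forces with `σ² = 2 γ kT`, modified velocity-Verlet
with `λ = 0.65`, reduced units `r_c = m = kT = 1`, bead density `ρ_b = 3`,
`γ = 4.5`, `Δt = 0.04`. Repeat units are beads of roughly 10 atoms; water
is explicit. The interaction table (`dpd_aij()`) uses `a_ii = 25`,
`a_PGMA,matrix = 40` (strong incompatibility driving phase separation),
`a_PGMA,water = 27` (near-theta: with the standard χ ≈ 0.286 Δa mapping at
ρ_b = 3, Δa = 2 corresponds to χ ≈ 0.57, i.e. marginal solvency), and the
LCST switch is `a_matrix,water = 25` (good, below LCST) ↔ `37` (poor,
above). These are stated model choices in the Groot–Warren convention, not
fitted quantities; all are exposed as arguments.

Thermostat and pressure were validated against oracles. The kinetic
temperature holds the set point within 3% in walled, grafted production
systems. The conservative-virial pressure of the pure fluid matches the
established DPD equation of state `p ≈ ρ kT + 0.101 a ρ²` within 5% at
`ρ_b = 5`. A subtlety worth recording: the 0.101 coefficient is the
high-density plateau of `(p − ρkT)/(a ρ²)` and is not yet reached at
`ρ_b = 3`; at ρ_b = 3 both this engine and an independent canonical
Metropolis Monte Carlo simulation of the identical conservative potential
give `p = 23.6` (coefficient ≈ 0.092), so the engine is checked against
the published fit where the fit applies and against an independent sampler
where it does not.

Walls: the substrate is a frozen wall-bead layer plus bounce-back
reflection, with a soft planar repulsion within one cutoff of both z
boundaries. The soft layer matters: bounce-back alone lets beads reach the
reflection plane ballistically, and the reflection is not exactly
energy-consistent with the velocity-Verlet half-kick, which measurably
heats the near-wall fluid; with the soft wall force, reflections are rare
and the thermostat stays on set point.

**Cross-linking.** All cross-linkable (GMA) beads start active; each step,
every active pair whose soft cores touch or interpenetrate (`r < r_c`)
forms a harmonic bond with probability 0.1, in randomized order, both
partners becoming inactive immediately (a bead consumed earlier in the
step is skipped later in the same step). The target cross-link fraction is
`ν_cr = 2 N_b / N_matrix × 100` with `N_matrix` the total matrix bead
count; linking stops at the target and leftover cross-linker converts to
plain matrix beads. The accounting identity is exact by construction and
is asserted in the tests. The GMA fraction during the cross-linking stage
is 30%, so the reachable ceiling is `ν_cr = 30%`.

**Swelling experiments.** The grafted matrix (chains of `N_chain` beads at
grafting density `ρ_g`, first bead anchored to the substrate) is built in
the collapsed state, pre-equilibrated, cross-linked in the collapsed state,
equilibrated and sampled for the collapsed height `h2`, switched below the
LCST, re-equilibrated and sampled for the swollen height `h1`. Heights are
first-moment brush heights `h = 2⟨z⟩`, the standard estimator (exact for a
uniform slab). Chains are initialized as compact random walks near the
substrate rather than stretched lines: the collapsed state is then a few
hundred steps away instead of tens of thousands. Swelling is the slow
direction; sampling windows are placed late and a drift flag marks runs
whose two half-window means differ by more than 10%.

**Cap-pinned geometry.** Two rigid spherical caps (height 10, radius
`R ∈ {30, 50, 100}`) sit at opposite box sides; by lateral periodicity
they form a domain array with separation `s` between cap feet. The box is
narrow in y and the caps are implemented as y-invariant circular ridges —
the sagitta across a 3–4 unit width is at most ~0.07 for `R = 30`, so the
curvature across the width is negligible. The matrix has two anchor
populations: chains grafted to the substrate strip between the cap feet at
density `ρ_g = 0.2`, and chains anchored to pin sites sampled on the cap
surface below height 7 at density `ρ_pd` — the copolymer is deposited over
the whole structure during fabrication and grafts to the epoxy-bearing
domain surface wherever it touches, so pinned chains are anchored on the
flanks directly at build time. (An earlier nearest-bead-after-contact
attachment scheme left the flank sites unreachable by the collapsed matrix
in small boxes and produced no pinning at all; anchoring at build time is
both simpler and closer to the fabrication chemistry.) As in
the source study's own account of this geometry, the network is *not*
fully equilibrated at the largest boxes; heights are recorded over a fixed
late window and flagged, and the reported quantities are trends, not
converged equilibrium values.

**Phase separation.** Tethered PGMA/matrix chains at PGMA mass fraction
`f` in the near-theta solvent demix into PGMA domains; PGMA beads are
clustered by single linkage at the interaction range and each cluster is
sliced and fitted with the spherical-cap model, with slice radii estimated
from bead counts at near-melt density. Only trends (domain size and height
growing with `f`; cap-fit consistency) are meaningful at desk scale.

## The Monte Carlo cell-sorting model

The surface is a periodic box of side `L = 240` with cylindrical adhesive
domains of diameter `D_d` (height `H_d = D_d`) placed by random sequential
adsorption at coverage `σ_d = 0.48` (domain count
`round(σ_d L² / π (D_d/2)²)`; pair centre distance ≥ `D_d`; the coverage
must stay below the disc-RSA jamming bound 0.547 for placement to
terminate). Cells are hard spheres of diameter `D = 10` that deform at
contact into a flat circular facet of radius `a = sqrt((D/2)² − h²)` (`h`
the centre height above the domain-top plane), with deformation depth
capped at `δ_max`. The adhesion energy is `A_kd` per unit contact area,
where the contact area is the sum of two-circle lens intersections between
the facet disk and the domain top disks — attraction only where domain
surface actually underlies the facet. In the swollen state the polymer
surface sits `h_p` above the domain tops and repels with `B_p` per unit
area of the circular cell cross-section at the polymer surface, minus the
lens intersections with domain disks (domains exclude polymer regardless
of polymer height); if the polymer plane passes below the cell equator,
the cross-section is clamped at the maximal disc `π(D/2)²`. Gravity adds
`g_w z`. Metropolis moves displace one uniformly chosen cell by a uniform
vector in a cube of half-width `Δ`, accepting with
`min(1, exp(−ΔE/T_eff))`; lateral coordinates wrap, a hard wall enforces
`z ≥ H_d + D/2 − δ_max`, and the top of the box reflects. All randomness
comes from an explicit xoshiro256+ stream seeded per run, so trajectories
are bit-reproducible.

Reduced units are fixed by the printed observables: `N = 200` cells on
`L = 240` give the monolayer number density `ρ_c = 3.472 × 10⁻³` and
packing fraction `N π (D/2)²/L² = 0.273` exactly, which forces `D = 10`
per `L = 240`; `T_eff ≡ 1` defines the energy unit. "Simulation steps"
are attempted single-cell moves. The box height is 40 (4 cell diameters):
the detached phase has thickness scale `T_eff/g_w = 10`, so attached
fractions are insensitive to the ceiling.

**Calibration of the unpublished parameters.** Four model parameters are
not published: the swollen polymer height `h_p`, the deformation limit
`δ_max`, the gravity strength `g_w`, and the move size `Δ`. They form the
single documented calibration required to reproduce the sorting working
points, chosen by a grid search *before* freezing and then used everywhere
unchanged:

* `δ_max = 3.25` (0.325 D). This is the physically load-bearing choice: the
  type-1/type-2 discrimination in the published working points (≈35%
  versus ≈3% remaining) requires an adhesion-energy gap
  `(A_1d − A_2d) · contact ≈ 3 T_eff`, i.e. a contact area ≈ 30 reduced
  units², which a facet limited to a shallow `δ_max ≈ 0.5` cannot supply.
  Under the calibrated value, type-1 cells press to full deformation while
  for type-2 cells deformation barely pays — the same asymmetry the
  push-off-force picture predicts.
* `h_p = 0.3`. Sets how far detached cells hover above the attachment
  cutoff and therefore the baseline of "attached" type-2 cells; small
  values leave the baseline too high, large values push the
  separation-factor maxima to implausibly high `B_p`.
* `g_w = 0.1` (adhesion ≈ 10–14 `T_eff` versus gravity ≈ 1 `T_eff` over a
  cell diameter — weak, as it should be).
* `Δ = 1.5`, tuned to ~40% acceptance during the attached stages.

Desk-scale stage lengths are 1.2 M attempted moves for adsorption and
1.5 M for desorption (the source protocol used 2 M with stationarity "much
earlier"; quarter-wise traces here are flat after the first quarter, and
attached fractions from 1.5 M agree with 4 M runs within the seed-to-seed
spread). Attached counts average over the final half of the desorption
stage; "attached" means the cell centre is within `r_cut = D/2` of the
domain-top plane.

The separation factor of a sweep point is the ratio of mean attached
fractions (type 1 / type 2) relative to the initial 1:1 ratio; the peak of
a sweep is taken as the grid argmax of that curve on a 0.025-resolution
`B_p` grid containing the working points 0.32 and 0.37. Where attached
type-2 counts approach zero the factor is noisy (a one-cell difference
moves it by tens of percent); this is a property of the observable itself,
and the acceptance driver therefore averages over 4 seeds.

## Problem sizes and tolerances used by the test suite

The test and acceptance runs use these desk-scale sizes, chosen to keep the
full suite within an ordinary interactive budget while leaving every
qualitative conclusion intact:

* MC working points and sweeps: `L = 240` (full scale), 1.2 M/1.5 M moves,
  3–4 seeds, `B_p` grid 0.27–0.445 step 0.025.
* DPD swelling band run: chain length 100, `ρ_g = 0.2`, box `8 × 8 × 32`
  (13 chains), ~40 k steps per run (~32 k of them swelling — the slow
  direction; the swollen height plateaus near 35 k steps and the reported
  band value is taken on the plateau).
* DPD trend runs: chain length 40 for the cross-linking/grafting trends
  (boxes `6 × 6 × 16`), chain length 30 for the cap-pinned trends
  (`R ∈ {30, 50}`, `s ∈ {10, 40}`, `ρ_pd ∈ {0.2, 0.6}`, `Ly = 3`,
  `Lz = 18`), 3 seeds each. The widest separation (`s = 40`) is used for
  the separation trend because the per-condition noise at these box sizes
  (±0.05–0.10 on the ratio) needs the full contrast the study design
  offers.
* Geometry oracles: 10⁵ sampling points, 1% tolerance; barometric KS test
  at p > 0.01; Metropolis frequency ±0.01 at 10⁴ trials.

## Known limitations

* The cell model has no hydrodynamics, no shear flow, no cell-cell
  adhesion, and only the flat-facet deformation; absolute detachment
  kinetics are therefore not comparable to flow experiments, only
  equilibrium-like remaining fractions.
* The height-map generator uses uncorrelated pixel noise and ideal caps;
  it does not emulate SPM tip convolution, scars, or drift, so analyzer
  performance on real scans will be somewhat worse than the round-trip
  tests suggest.
* The DPD force field is a stated parameterization in the standard
  convention, not a fit to the specific chemistry; LCST switching is a
  solvent-quality jump, not a thermal model.
* Desk-scale cap-pinned runs are deliberately non-equilibrated (flagged),
  matching how those geometries are reported in the source study; their
  swelling ratios are comparable *between* conditions, not as absolute
  values.
* The separation-factor peak location has an intrinsic resolution of the
  `B_p` grid (0.025) and, at the peak, a seed-to-seed spread of one grid
  step.
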