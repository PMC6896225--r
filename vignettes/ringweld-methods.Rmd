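---
title: "ringweld: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringweld: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

The membrane rotor of ATP synthase is a ring of identical two-helix
subunits whose central pore is plugged by lipids. `ringweld` models the
biased assembly of such a ring at a deliberately coarse, desk-computable
scale: two rigid half-rings embedded in a bead membrane are pulled
toward a reference structure by harmonic positional restraints, trapping
lipids inside, and the resulting configurations are analysed with the
same density-map and trajectory statistics one would apply to the
full-scale problem.

## Geometry

A protomer is two rigid vertical columns of beads (default 3 beads per
column) standing for its two transmembrane helices, placed on concentric
circles (outer 2.6 nm, inner 1.7 nm) about the ring axis, which is +z
through the box centre. These radii are placeholders that give a
ring-sized pore; they are not measurements of any particular ring. A
lipid is a rigid 3-bead rod (head + two tails); its leaflet is named for
the protein feature that faces it — `loop_side` (+z by package
convention) and `nc_side` (−z). The default box is 24 × 18 × 12 nm, the
size used for the corresponding coarse-grained assembly systems, with
the membrane plane periodic in x,y and the normal non-periodic.

The default bulk bath density is 1.5 lipids/nm² per leaflet (the area
density of a POPC leaflet, ~0.65 nm² per lipid). Plug lipids sit on a
hexagonal grid (0.7 nm spacing) inside the pore; bulk lipids on a
jittered hexagonal grid outside the protein footprint, gap between the
half-rings included — so the closing ring must extrude excess gap lipids,
the behaviour the extrusion detector measures. Lattice spacings are made
commensurate with the box so the periodic seam introduces no close
contacts, and generators assert the no-overlap invariant (head–head
distance > bead diameter).

## Dynamics

The integrator is first-order (overdamped / Brownian) Euler–Maruyama:

    x ← x + (F/γ) Δt + sqrt(2 kB T Δt / γ) ξ

The protocol logic being modelled — bias stages, convergence tests,
trapping — is integrator-agnostic, so the simplest testable stochastic
dynamics is used; no thermostat, barostat, electrostatics or solvent
beads. Protomers and lipids move as rigid bodies: net force and torque
map to an in-plane translation plus a rotation about the body's own
vertical axis, with protomer z and tilt frozen (membrane-embedded
approximation) and lipid z free, so the leaflet-confinement term can act.
Treating lipids as rigid rods is also what keeps 3-bead molecules intact
under a force field that has no intramolecular bonded terms.

Forces are exactly three terms, each with an analytic gradient checked
against central differences in the tests:

1. **WCA repulsion** between beads of different molecules, cut at the
   sum of the bead radii (force and potential continuous at the cutoff).
   Purely repulsive: the bath is a fluid of soft disks, with no cohesion
   to mimic.
2. **Leaflet confinement** on lipid head beads,
   `Fz = −k_leaflet (z − z_target)`, with targets ±1.4 nm about the
   bilayer midplane.
3. **Positional bias** on protomer beads, `F = −k_bias (x − x_ref)`, the
   per-bead lab-frame restraint that drives assembly (the analog of a
   position-restraint file pointing at the experimental structure).

Randomness comes from R's RNG (`set.seed` governs the compiled core
too), so every run is bit-reproducible from its seed.

# Parameters, units and the toy scaling

Internal units are nm, ps and kJ/mol; the density-map layer works in
ångströms, with the factor of 10 applied only at that boundary. RMSD is
reported in Å.

| Parameter | Default | Why |
|---|---|---|
| temperature | 303 K | matches the atomistic reference conditions |
| γ (per bead) | 500 kJ·ps·mol⁻¹·nm⁻² | sets the weak-stage relaxation time γ/k to 25–250 ps across the spring-constant scan, so convergence happens within a 300 ps stage while approach speeds (~0.05 nm/ps) stay slow enough for bath lipids to yield; at lower friction the bias plows the half-rings through the bath faster than lipids can respond and the explicit Euler step destabilises |
| Δt | 0.04 ps | stability: kΔt/γ = 0.08 at the strongest restraint (k = 1000), comfortably inside the overdamped Euler bound of 2 |
| bead radii | 0.25/0.23/0.15 nm | protomer/lipid/water contact distances below the ring's inter-column spacing (~0.96 nm), so the reference structure is not self-repelling |
| ε (WCA) | 2.5 kJ/mol ≈ kBT | soft fluid-like contacts |
| k_leaflet | 5 kJ/(mol·nm²) | holds heads within ~0.7 nm of their leaflet at 303 K without freezing z |

**Weak-stage spring constants are the full-scale scan values × 1000**
(i.e. {2, 5, 10, 20} kJ/(mol·nm²) per bead, default 10). The scaling is
forced by equipartition: a rigid body restrained by N per-bead springs k
has positional variance kB T/(N k) per degree of freedom. A full-scale
half-ring has thousands of restrained particles, so k ≈ 0.01 gives Å-scale
localisation; a toy protomer has 6 beads, and the same k would give a
spread of several nm — no convergence threshold in the Å range could ever
be crossed. Multiplying by 10³ restores the same N·k product scale. The
scan preserves the original 1 : 2.5 : 5 : 10 ratios, and the package
tests the *ordering* of mean convergence times across the scan, never
the full-scale absolute times (µs) or lipid counts, which are explicitly
not reproduction targets.

The staged strong restraints are used verbatim — 10, 100 and
1000 kJ/(mol·nm²) for 200 ps each — because at these magnitudes the
per-bead equipartition argument gives sub-Å spreads (≈0.35 Å total RMSD
at k = 1000) for the 6-bead protomer too; the schedule ends below
0.8 Å without any rescaling.

## Protocol and classification

The weak stage runs until the lab-frame protomer RMSD drops below the
convergence threshold (default 5 Å, chosen to cover the 3.0–4.7 Å band
in which converged weak-stage assemblies typically land) or its budget
(default 300 ps) expires. Only converged runs proceed to the strong
stages; a run that never converges is classified `not_assembled` — which
is also why zero-bias controls correctly fail rather than being rescued
by the strong restraints. The convergence time is the first *sampled*
time strictly below threshold (no interpolation; sampling interval
1 ps). RMSD for convergence is lab-frame over protomer beads only,
because the bias itself is defined in the lab frame; the Kabsch-fitted
variant exists for reporting. Whether full-scale convergence traces used
protomer-only or all-particle RMSD is not stated in the sources this
design follows; protomer-only is the package's choice.

# The analysis stack

**Ring region.** The "inner volume" is formalised as the simple polygon
of outer-column protomer centroids ordered by azimuth (for split
half-rings this single polygon spans both halves and the gap), bounded
vertically by ±2 nm (the bilayer span) about the mean protomer z.
Boundary points count as inside; this affects only measure-zero
configurations and is documented rather than load-bearing. Within a
protomer, the outer column is identified geometrically (the half of its
beads farther from the ring centroid), so the definition survives
arbitrary rigid motion.

**Leaflets** are assigned per frame from the sign of the head height
above the midplane, so flip events would be tracked rather than frozen
at construction.

**Residence times** are maximal runs of consecutive inside frames;
duration is `(t_last + Δt) − t_first` with per-gap Δt for irregular
sampling; records touching either trajectory end are censored and
excluded from summaries by default (the survival-analysis-correct
choice), includable by flag.

**Extrusions** are inside→outside transitions not reversed within a
debounce window (default 10 frames) — the debounce suppresses boundary
flicker, and is exposed as a flag.

**Densities** are volmap-style: each selected bead deposits a normalised
isotropic Gaussian (unit integral, truncated per axis at 4σ), per-frame
grids averaged. Default sampling is 1 Å; kernel σ defaults to 1 Å and is
exposed because no standard value exists for the full-scale tool either.
Symmetry averaging rotates the map in 360/n° increments with trilinear
inverse-mapping resampling and zero fill; masks threshold strictly above
the level (default 0.8, the convention for selecting the simulated
pore volume; display levels are a visualisation default only, not used
in computation). RSCC is the Pearson correlation over masked voxels —
scale-free, which is exactly why no absolute density calibration between
simulated and reference maps is attempted. Map-to-map comparison assumes
a shared coordinate frame; rigid map alignment is out of scope.

# Numerical choices

- Trilinear resampling is exact on affine fields and on a grid's own
  lattice; its error on smooth maps scales as h²/(8σ²) per rotation.
  The symmetry-averaging fixtures therefore use σ = 4 Å blobs on a 1 Å
  lattice, where the analytic n-blob oracle agrees within 1% of the
  peak; interpolation tolerance is stated with each test.
- The compiled pair loop uses a cell list over the periodic membrane
  plane (cells ≥ cutoff) and falls back to an all-pairs loop for small
  or narrow boxes, where wrapped cell neighbourhoods would double-count.
- Divergence (non-finite coordinates or per-step displacements above
  1 nm) raises an error naming the step, never a silent clamp.
- The equipartition validation uses kΔt/γ = 0.02, where the known
  Euler–Maruyama discretisation bias of the stationary variance,
  1/(1 − kΔt/2γ), is 1% — small against the 5% acceptance band — and
  the ~50-step autocorrelation time leaves ~10⁴ effective samples in a
  10⁶-step run (≈1.4% standard error on the variance).

# What the fixtures do and do not show

The synthetic generators produce systems with *exact* ground truth:
Cₙ-symmetric rings (to machine precision, for n = 3…17), density maps
evaluated analytically per voxel, and scripted trajectories whose
inside/outside intervals, contact distances and head-height shifts are
realised exactly. Passing tests therefore demonstrate that the
machinery — classification, residence bookkeeping, kernels, rotation
resampling, correlation — is correct, not that the toy physics
reproduces any full-scale quantity. Real membranes have lipid chemistry,
cohesion, solvent and electrostatics this model deliberately lacks.

Two fixture-design points deserve emphasis:

- **Residence/displacement recovery** uses scripted data (exponential
  dwells, mean 50 ns, n = 200; a +0.3 nm noisy plug shift), so the test
  is parameter recovery by the analysis pipeline, with sampling error
  (~7% at 2σ for the dwell mean) inside the stated 15% and 0.02 nm
  bands.
- **RSCC model selection** compares 7/10-plug and 6/9-plug densities
  against an independent realisation of the 7/10 system (the stand-in
  for an experimental map). The plug fixture is simulated *cold* (30 K)
  under a restrained ring: at 303 K the pore lipids behave as a 2-D
  liquid whose time-averaged density forgets the plug arrangement
  within picoseconds, which is physically reasonable but leaves nothing
  for a pattern comparison to discriminate on desk-scale averaging
  windows. The cold plug preserves the ground-truth arrangement, so the
  test isolates the property of interest: that the masked-RSCC
  machinery ranks the matched composition above the mismatched one, in
  both directions.

# Problem sizes

The default study conditions are the full 24 × 18 × 12 nm box
(~1176 bath lipids, 3612 beads). The five-seed staged protocol
(~750 ps each) and the four-point spring-constant scan with five seeds
each are run at these conditions; validation quantities use smaller
dedicated systems (a single bead for equipartition, plug-only systems
for density comparisons, scripted trajectories for recovery tests).

# Known limitations

- Protomer tilt and z are frozen; assembly defects that involve tilting
  cannot occur, so the not-assembled outcomes here are lateral traps
  only.
- The spring constant applies per bead; full-scale restraint files do
  not state a per-what convention, and per-bead is the simplest choice.
- No pressure coupling: the box is constant-volume, so the full-scale
  detail of scaling the reference structure with the barostat matrix has
  no analog and is dropped.
- Lipid extrusion and trapping counts depend on the toy bath density
  and WCA radii; they are qualitative analogs (more lipids trapped than
  fit comfortably; excess extruded under strong restraints), not
  predictions.
- The weak-stage scan occasionally shows non-monotonic assembly success
  between adjacent spring constants, as full-scale scans do; only the
  average ordering of convergence times is a tested property.
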