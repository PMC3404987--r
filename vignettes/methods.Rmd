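---
title: "Methods: bilayer observables, the synthetic configuration model, and pore calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer observables, the synthetic configuration model, and pore calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dmsopore` quantifies how DMSO reshapes DOPC/cholesterol bilayers. This
vignette is the package's account of the science: the observables and their
definitions, the statistical configuration model that stands in for
molecular dynamics, the numerical choices, and what the tests do and do not
establish about real data.

## Coordinate conventions

Coordinates are in nm with the bilayer normal fixed to z; the membrane is
never de-tilted. Positions are wrapped to `[0, L)` on every axis; pairwise
analyses use the in-plane (x, y) minimum image, intramolecular vectors the
full 3-D minimum image. Leaflets are split at the mean phosphate z
(ties go to the lower leaflet, for determinism); the outward normal is +z
for the upper leaflet and −z for the lower.

The scaled membrane coordinate Z′ places each leaflet's phosphate-density
maximum at ±1 and the bilayer centre at 0. Each side is scaled by its own
peak distance, so asymmetric membranes still map their peaks to exactly ±1.
The scaling is computed once per analysis window (not per frame), because
profiles are reported as one curve per condition.

## Observables

**Density and PMF.** ρ(z) histograms atomic masses over uniform z bins
(default width 0.05 nm, chosen to resolve the headgroup peaks at generator
scale) and divides by the bin volume; mass is conserved exactly by
construction. The free-energy profile is the Boltzmann inversion
ΔG(z) = −RT ln(ρ(z)/ρ₀) with R = 8.314 J·mol⁻¹·K⁻¹ and T = 310 K by
default. ρ₀ is the mean density over the bulk region, |Z′| > 1.5 by default
(configurable; the definition of "bulk" is a choice, so the functions also
accept an explicit ρ₀ and bulk mask). Bins with ρ = 0 are flagged
unbounded, never imputed — a finite value there would be an artefact of
short sampling — and barrier heights are maxima over finite bins with the
flag count reported. The additive gauge is fixed so the mean ΔG over finite
bulk bins is exactly zero.

**Chain order.** S_CD = ⟨(3 cos²θ − 1)/2⟩ for the C–H(D) bond direction
against the normal; −S_CD is reported so that larger means more ordered.
The configurations are united-atom, so the two hydrogen directions at each
interior carbon are reconstructed assuming ideal tetrahedral geometry:
perpendicular to the C(i−1)→C(i+1) axis, symmetric about the local chain
plane, H–C–H angle 109.47°. Explicit hydrogens would take precedence, but
the generator does not emit them. The double-bond carbons of the oleoyl
tails are not special-cased — the generator carries no bond-order
information, and the simplification is uniform across conditions. The mean
order parameter is the average over all CD segments.

**Tilt.** The acyl vector runs first→last tail carbon (a principal-axis fit
is a reasonable alternative; first→last was chosen for transparency and
because the two differ negligibly for the generator's chains). The
cholesterol axis runs hydroxyl-O→last ring-axis carbon. Angles are measured
against the molecule's leaflet outward normal and folded to [0°, 90°]
(vector vs axis): reference tables report acute angles only.

**Lateral correlation.** C(r) is the 2-D radial distribution of DOPC
centres of mass, computed per leaflet (cross-leaflet pairs are excluded —
in-plane organization is a monolayer property) and then averaged. Ordered
pair counts per annulus are normalized by the exact annulus area times
(n − 1)/A times the reference count, so an ideal gas gives exactly 1 and
the normalization integrates back to the counted pairs identically.
Molecule centres of mass are unwrapped relative to each molecule's first
atom before wrapping.

**Dipole orientation.** The DMSO dipole is the O→S vector, the water dipole
the bisector of the two O→H bonds — both point from the negative to the
positive end. Angles are taken against the outward normal of the nearer
leaflet (by the sign of Z′) and binned by Z′; an isotropic orientation
averages to 90°, the natural baseline. In systems without phosphates
(solvent-only boxes) the raw distance to the box midplane is used instead.

## The synthetic configuration model

Frames are independent statistical draws — no forces, no dynamics. Every
analysis in the package is an ensemble average, so i.i.d. frames with the
right single-frame statistics are sufficient ground truth; what they cannot
provide is realistic time correlation (see Limitations).

Defaults are the reference composition: 128 DOPC, 20 mol% cholesterol
(32 Chol, both counts split evenly over the leaflets; molecule counts round
to nearest with ties away from zero, which reproduces 128/32 and
6186 → 619 DMSO at 10 mol%), 6186 solvent molecules, phosphate planes at
±2.085 nm (P-P distance 4.17 nm), mean −S_CD 0.1528, tail tilt 28.26°,
Chol tilt 30.88° — the DMSO-free reference state. DOPC is reduced to the
sites the analyses consume: a phosphate marker plus choline- and
glycerol/ester pseudo-atoms that carry the remaining headgroup mass
(104.17 and 143.84 amu, so the lipid's ~786 amu sit where the real groups
sit and the density profile peaks at the phosphate planes), and two
18-carbon united-atom tails. Cholesterol is a hydroxyl oxygen plus a
straight 8-carbon ring axis; water is 3-site rigid with the dipole along
the bisector; DMSO is S, O and two methyl carbons.

**Chain order control.** Tail segments follow a von Mises–Fisher
distribution about the chain axis; each chain's segment set is rigidly
rotated so its end-to-end vector lies exactly along the drawn axis. This
decouples the two targets: the tilt distribution (normal, sd 3°, truncated
to [0°, 90°]) controls the end-to-end tilt exactly, while the vMF
concentration κ controls the wobble and hence −S_CD. κ is solved by
bisection against a Monte-Carlo evaluation of the order parameter *as the
analysis measures it* (same tetrahedral reconstruction, same tilt
distribution, fixed internal seed, 12 000 chains per evaluation), so the
analysis recovers the target by construction up to sampling error. The
solution is cached per (target, tilt) pair. Targets above the geometric
maximum (≈ P₂(cos tilt)/2, reached by straight chains) are refused with a
warning. An all-trans chain parallel to the normal gives −S_CD = 0.5 and
the magic angle (54.74°) gives 0, which the tests assert.

**Solvent.** Water z-positions are rejection-sampled from a piecewise
relative density: bulk-constant outside the phosphate planes, decaying
geometrically to `water_core_penetration` (default 0.05) at Z′ = 0. DMSO
mixes a bulk component with an interfacial Gaussian centred 0.15 nm inside
each phosphate plane (width 0.35 nm, interfacial fraction 0.5 by default) —
the amphiphile accumulates just below the headgroups. Interfacial DMSO
dipoles follow a truncated normal around `dmso_dipole_mean_angle`
(default 110°, past the 90° isotropic baseline, i.e. oxygen toward the
polar region); interfacial waters (within 0.45 nm of a phosphate plane) are
biased H-toward-membrane (mean 105°, sd 15°); everything else is isotropic.
A 0.25 nm minimum distance between solvent heavy atoms is enforced by
sequential rejection with a retry cap (waters and DMSO each against their
own kind), which prevents the zero-distance clusters that would break the
pore detector. This exclusion slightly inflates the core-to-bulk water
ratio relative to the sampling density (dense regions lose more
candidates), so the core-penetration recovery test runs with exclusion off.

**Undulations** are a single product mode of amplitude
`undulation_amplitude` applied to the lipid planes. The reference work
observes increased undulation qualitatively but provides no spectrum, so
the default is 0 (flat) and no quantitative target is attached to this
knob.

**Planted pores.** Columns are built by *relocating* bulk waters (always
the same molecules, so tracked events overlap across frames) onto a
single-file line spanning the inter-phosphate slab with spacings safely
below the clustering cutoff; topology and atom counts never change, which
keeps the trajectory invariants intact. Hydrophilic pores additionally
translate lining DOPC molecules — drawn evenly from both leaflets so
neither mean phosphate plane is dragged toward the centre — to put their
phosphates within the lining radius near the slab centre. Planting is
deterministic (no RNG) and the ground truth is recorded on the trajectory.

## Pore calling

Thresholds are pre-registered constants, echoed in every output:

| threshold | default | rationale |
|---|---|---|
| O–O cutoff | 0.35 nm | first hydration-shell distance |
| slab margin | 0.30 nm | excludes ordinary headgroup hydration water |
| lining radius | 0.60 nm | headgroups this close to the axis line the pore |
| lining count | ≥ 6 | a lined (hydrophilic) pore |
| stability | ≥ 10 frames or persists to trajectory end | separates "stable" from "very transient" |
| track linkage | ≥ 1 shared water | single-file columns exchange members rapidly |
| multi-pore | ≥ 3 simultaneous | membrane-destruction regime |

Reference descriptions of these pores are qualitative (visual), so the
lifetime and lining thresholds are artifact decisions, not literature
values; every output echoes them. Slab waters are clustered by
single-linkage (union-find over contact pairs); the test suite holds the
partition against an independent brute-force breadth-first-search oracle
exactly. A spanning defect must reach within one cutoff of both slab faces.
Classification: stable lifetime *and* lining met (in at least half the
event's frames) → stable hydrophilic; neither → transient hydrophobic;
mixed cases (e.g. a long-lived bare column) are INDETERMINATE and flagged
rather than forced into a class. Regimes: III on any frame without two
separated phosphate planes *or* ≥ 3 simultaneous spanning defects (both
readings of "membrane destruction" trigger it, since the boundary between
them is ambiguous); else II with ≥ 1 stable hydrophilic event; else I.
Trajectories shorter than the stability threshold return UNDETERMINED.
DMSO sites may optionally join defect membership (they wrap nascent water
columns) but never count toward the lining criterion, which is a lipid
headgroup property; the default is water-only membership.

## Mixture conversions

vol% → mol% assumes ideal (excess-free) volume mixing with
ρ = 1.10/1.00 g·mL⁻¹ and M = 78.13/18.02 g·mol⁻¹. Real DMSO/water mixing
is slightly non-ideal; at the two-decimal precision of the reference pairs
(10 → 2.74, 20 → 5.97, 30 → 9.79, 40 → 14.5 mol%) the ideal model
reproduces all four within ±0.05 mol% (±0.04 at 40 vol%), and the
mole-to-volume inverse is exact algebra, so the round trip is an identity.

## Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, the package's own choice
of problem size: bilayers of 16–128 lipids, 120–6186 solvent molecules,
6–20 frames; the PMF oracle uses 10⁵ single-site waters × 20 frames
sampled from exp(−U/RT) with a 10 kJ·mol⁻¹ Gaussian barrier (recovery
within 0.5 kJ·mol⁻¹); the isotropic orientation baseline uses 5×10⁵
DMSO molecules (≥ 10⁵ per bin, mean 90° ± 0.5°); the pore suite uses 20
ten-frame trajectories. Degenerate inputs fail loudly with the decision
that caused them named (undefined ρ₀, missing phosphates, one-lipid
leaflets, oversized pore radii, r_max beyond the half-box).

## What the tests show — and what they cannot

Passing parameter-recovery tests show that the analyses measure what the
generator planted, under the generator's assumptions: i.i.d. frames, flat
(or single-mode) membranes, axially symmetric chain statistics, planted
rather than emergent pores. They do not validate behaviour on real MD
output with correlated frames, undulation spectra, chain kinks from
double bonds, lipid protrusions, or pores formed by actual physics; pore
*lifetimes*, in particular, are meaningful only relative to the i.i.d.
frame structure. The absolute structural numbers produced by the reference
simulations (areas, thicknesses, order parameters as functions of DMSO
content) are inputs here — generator targets and worked-example
arithmetic — not predictions of this package.
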