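---
title: "Coarse-grained helix models and static bundle electrostatics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained helix models and static bundle electrostatics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixforce)
```

helixforce estimates the net static electrostatic interaction force inside an
alpha-helix bundle — for example the four- and five-helix coiled-coil
sub-domains of the talin rod, whose unfolding under 5–25 pN tension drives
mechanotransduction signalling. Rather than integrating an energy field as
molecular dynamics does, it works directly in the force domain: each helix is
reduced to a rigid cylinder-and-spheres object carrying integer point
charges, helices are placed in a common simulation frame by rigid-body
transforms borrowed from robot kinematics, and Coulomb's law is summed over
inter-helix charge pairs. This vignette documents the model, its
assumptions, the tunable parameters, and the numerical decisions.

## The coarse-grained helix model

The unit of modelling is one annotated helix: a contiguous residue range on
one chain. Two assumptions define the coarse graining:

1. **Straight, rigid axis.** The helix is a straight cylinder. Each residue's
   backbone is collapsed to its Cα position; the axis is the first principal
   component of the Cα trace, computed by SVD of the covariance matrix
   `S = BᵀB/(n−1)` of the zero-mean positions (denominator `n − 1`). The axis
   segment runs between the orthogonal projections of the first and last Cα
   onto the fitted line through the centroid, so start, centroid and end are
   collinear and the segment runs N→C. The cylinder radius is the mean of the
   per-residue perpendicular (true Euclidean) distances to that line.
2. **Sidechains as spheres.** Each sidechain is a sphere centred at the mean
   of its heavy-atom positions, with radius the mean distance from that
   centre to the atoms. Sidechains rotate nearly freely about the Cα–Cβ
   bond, which makes a sphere a reasonable orientation-free summary. Glycine
   has no heavy sidechain atoms: its sphere sits at the Cα with radius 0 and
   carries no charge.

The axis direction from an SVD is defined only up to sign; we fix it so that
`direction · (b_n − b_1) > 0`, i.e. the axis points N→C along the annotated
range. This makes frames reproducible across runs and structures.

### Finite-length axis tilt

A subtlety worth knowing: for a *short* discrete helix the variance-maximising
axis is genuinely tilted away from the geometric (generator) axis, because an
incomplete final turn leaves nonzero cross-covariance between the axial and
transverse coordinates. This is a property of the estimand, not an
implementation artefact — a brute-force search over directions maximising the
projected variance agrees with the SVD axis to better than 0.01°, while both
sit ≈2.2° off the true axis at 18 residues. The tilt decays roughly with the
square of the helix length: ≈0.5° at 36 residues, ≈0.13° at 72. Consequently
the per-residue radial distances about the *fitted* axis oscillate slightly
even for a perfectly constant-width helix; the skew regression (below) is
insensitive to this symmetric oscillation, which is one reason it is the
right validation statistic. The package's recovery study (tests and the
acceptance script) therefore uses 36-residue helices — ten full turns,
≈54 Å, the length scale of talin rod helices.

## Local frames and bundle placement

Every helix carries a local coordinate frame expressed as a homogeneous
transform in Craig's convention (a 4×4 matrix with rotation columns `x̂ ŷ ẑ`
and translation `p₀`, bottom row `0 0 0 1`):

- `x̂` — the fitted axis direction;
- `ŷ` — from the axis toward the centre of the first *significant*
  (non-glycine) sidechain. As printed, the vector from the sidechain's axis
  foot point to its centre need not be exactly perpendicular to `x̂` in
  floating point, so we additionally Gram–Schmidt it against `x̂`: a rotation
  matrix must be exactly orthonormal before `ẑ = x̂ × ŷ` can complete a
  right-handed triad;
- origin — the axis start (the N-terminal end of the segment).

Frame names travel with each transform and are checked at composition time;
composing transforms whose frames do not chain raises an error immediately,
which catches the classic transform-direction bug. The simulation (SIM)
frame is anchored by setting the transform from the first helix's frame to
SIM to the identity; every helix is then re-expressed in SIM coordinates by
the one common rigid motion, so all relative geometry recorded in the source
structure is preserved to machine precision. The relative transform between
two helix frames (through any intermediate linker frame) is observable only
as a product, so only the product is represented.

## Charges and the static force

Charges are integers in {−1, 0, +1}, assigned by residue type at pH 7.2:
aspartate/glutamate −1, lysine/arginine +1, everything else 0. Histidine's
sidechain pKₐ (≈6.0) leaves it <10 % protonated at pH 7.2, so the default
table maps it to 0; the table is overridable (e.g. `charge_table(overrides =
c(HIS = 1))`) for sensitivity analyses. The residue's whole charge sits at
its sidechain sphere centre.

For every unordered pair of helices in the bundle, Coulomb's law

$$F = k_e \frac{q_1 q_2}{\epsilon_r r^2}$$

is evaluated for every cross pair of charged sites (intra-helix pairs are
excluded), with $k_e = 1/(4\pi\epsilon_0) = 8.9875517873682\times10^9\,
\mathrm{N\,m^2\,C^{-2}}$, charges in elementary-charge units, distances in
Å converted to metres, and the result reported in pN. Positive is repulsive,
negative attractive. The default `relative_permittivity` is 1 — vacuum, no
solvent screening — which is the regime in which the published per-bundle
values were computed; it is configurable for exploration.

The headline number per bundle is the **signed scalar sum** of all pair
forces. The source analyses report one signed scalar per bundle without
defining the combination; a scalar sum is the only combination that makes
the published sign convention (negative = net attraction) exact, so that is
what `bundle_static_force()` returns, in a fixed summation order (helix
pair, then site indices) so totals are bit-reproducible. A per-helix 3-D
vector sum is also emitted for inspection, but it is not the headline
number. Coincident charged centres (< 10⁻⁶ Å apart) are an error rather
than an infinity.

## The synthetic generator

`generate_ideal_helix()` places Cα atoms on the parametric helix
`origin + axis·rise·k + radius·(cos kθ·u + sin kθ·v)` with canonical
defaults: rise 1.5 Å/residue, twist 100°/residue, Cα radius 2.3 Å,
right-handed for positive twist. `N`, `C`, `O` backbone atoms sit at fixed
bond-length-scale offsets; each sidechain is a seeded atom cluster whose
centroid sits exactly `sidechain_distance` (default 2.5 Å) radially outward
from the Cα. Two noise scales exist:

- `jitter_sd` (default 0) — isotropic Gaussian noise on each Cα placement
  and each sidechain centroid. With it at 0 every Cα is exactly 2.3 Å from
  the true axis, which the tests verify. It perturbs the backbone as well as
  the sidechains because a recovery study that only jitters sidechains would
  say nothing about the axis and radius estimators.
- `cluster_sd` (default 0.3 Å) — spread of the atoms within one sidechain
  cluster; clusters are re-centred so the centroid is exact regardless.

`generate_charged_pair()` builds two phase-aligned parallel helices, the
second a pure translation of the first, so corresponding sidechain centroids
are exactly the requested separation apart; charges are encoded by residue
type (LYS/ASP/ALA for +1/−1/0). This yields closed-form expected forces:
a single +1/−1 pair at 10 Å must give −230.7 pN end to end through the
real PDB writer, parser, fit, placement and force stages.

What the generator does **not** emulate: curved or frayed helices, real
backbone stereochemistry, rotamer distributions, correlated (B-factor-like)
noise, crystal contacts, or solvent. Passing the recovery tests therefore
demonstrates the estimators are correct for straight helices with isotropic
noise — it does not validate the straight-axis assumption on real coiled
coils. That validation is exactly what the diagnostics are for.

## Diagnostics

- **Radial profile / skew regression.** Per helix, the radial distances
  `l_i` are regressed (OLS) on the axial position `t_i` (both in Å; `t_i` is
  the arc position of the Cα's foot point from the axis start). The *skew
  angle* is `atan(slope)` in degrees — the angle between the fitted line and
  the constant mean-radius line. Near-zero skew across a set of helices
  supports the constant-width approximation. The angle, not the slope, is
  reported because it is what the published distribution summarises;
  sub-degree values are the expected scale.
- **Radial histogram.** Pooled `l_i` binned at a fixed width (default
  0.05 Å) with a moment-matched normal (sample mean/sd). Moment matching is
  used because nothing downstream needs a likelihood fit.
- **Sidechain shape statistics.** Every instance of a residue type is
  translated so its Cα is at the origin and rotated (minimal rotation) so
  its Cα→centroid direction lies along +x; the rotation *about* that axis is
  left free, exactly as the pooled-cloud construction implies, and distance
  statistics are invariant to it. Distances are measured from the pooled
  centroid; mean, median and quartiles are reported.

## Input handling decisions

PDB reading accepts fixed-column `ATOM` records only: HETATM (waters,
ligands) and hydrogens are excluded (the X-ray templates lack hydrogens;
including them only for NMR ensembles would bias sidechain centroids), and
altLoc markers other than blank/`A` are dropped to keep a single conformer.
Multi-model NMR files are gated on a `model_index` (default: first model).
Residue numbers are taken verbatim from the file; insertion codes are
rejected rather than silently merged, and nonstandard residues inside an
annotated range are an error (outside, they are simply never selected).
Helix ranges are user input — the analysis that produced the published
per-bundle values derived them manually from secondary-structure overlays
and never published them, so no attempt is made to re-derive them
automatically.

## Numerical choices, edge cases

- Axis endpoints by *orthogonal projection* of the terminal Cαs; a literal
  reading of the usual parametric-line shorthand would place both endpoints
  on the same side of the centroid, contradicting the stated start/end
  semantics.
- Radial distances use the true Euclidean norm (they are distances in Å,
  and are plotted as such), not the squared norm.
- Degenerate inputs raise classed errors, never NaNs: all-coincident points,
  zero-length axes, all-glycine helices (no frame reference), sidechain
  centres on the axis, coincident charged sites, fewer than 4 residues for a
  fit, fewer than 3 points for a regression.
- A single-helix "distribution" reports sd = 0 with `n = 1` rather than NA,
  so downstream tables stay numeric.
- Model documents serialize to JSON with full precision (`digits = NA`) and
  round-trip exactly up to the text representation.

## Problem sizes

The test-suite and acceptance-script studies use: 50 seeded helices of 36
residues (recovery and skew statistics), bundles up to 5 helices × 40
residues against the brute-force Coulomb oracle, and 4-residue minimal pairs
for closed-form force checks. These sizes give sub-minute runs while leaving
every estimator in its intended regime.

## Known limitations

Only the electrostatic term is modelled: hydrophobic packing, van der Waals
contacts and hydrogen bonds — all of which act attractively at bundle core
distances — are absent, so absolute net forces should be read as a single
interaction component, not a folding free-energy surrogate. Helices are
straight and rigid; curved helices in real coiled coils are approximated by
their best straight axis. Linker regions between helices are not modelled.
The static analysis gives one configuration's force; no dynamics, no
unfolding trajectories.
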