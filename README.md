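# helixforce

Coarse-grained alpha-helix models and static electrostatic force estimation
for helix bundles.

Mechanosensitive coiled-coil proteins — the canonical example being the 13
four- and five-helix bundles of the talin rod domain — unfold when the
tension across a bundle exceeds a threshold in the 5–25 pN range, exposing
cryptic binding sites and converting mechanical load into signalling.
Understanding which bundle unfolds at which force requires an estimate of
how strongly the helices of a bundle hold on to each other. All-atom
molecular dynamics overshoots measured unfolding forces by orders of
magnitude and cannot report inter-helix forces directly; helixforce instead
works *in the force domain*: each helix becomes a rigid cylinder-and-spheres
object with integer point charges, helices are placed in a common simulation
frame by rigid-body transforms (robot-kinematics style homogeneous
transforms in Craig's convention), and the net static electrostatic force of
the bundle is the signed scalar sum of Coulomb pair forces

$$F = k_e \frac{q_1 q_2}{\epsilon_r r^2}, \qquad k_e = \frac{1}{4\pi\epsilon_0},$$

over every cross pair of charged sidechains between every pair of helices
(negative = attractive, positive = repulsive; charges are integers in
{−1, 0, +1} assigned at pH 7.2: ASP/GLU −1, LYS/ARG +1, HIS and all others 0).

The package is aimed at structural biologists and biophysicists who want a
seconds-scale, interpretable inter-helix force estimate from a PDB structure
plus a table of helix residue ranges, and at method developers who need a
fully synthetic, ground-truth test bed for helix-geometry estimators.

## What it does

- **`read_structure()` / `read_helix_annotations()` / `group_residues()`** —
  parse fixed-column PDB `ATOM` records (model-aware for NMR ensembles,
  heavy atoms, single conformer) and split annotated helices into
  backbone/sidechain residue groups.
- **`build_helix_model()`** — fit the coarse-grained model: Cα centroid,
  SVD principal axis (sign-fixed N→C), projected axis endpoints, mean radial
  distance as the cylinder radius, one mean-position/mean-spread sphere per
  sidechain, and a local coordinate frame (x along the axis, y toward the
  first non-glycine sidechain).
- **`place_bundle()` / `ht_compose()` / `ht_invert()` / `ht_apply()`** —
  homogeneous-transform algebra with frame-name checking; the SIM frame is
  anchored to the first helix by an identity transform.
- **`assign_charges()` / `bundle_static_force()`** — pH-7.2 integer charges
  and the per-pair / per-helix-pair / net Coulomb force report (pN), with
  `tidy()`, `glance()` and `autoplot()` methods.
- **`radial_profile()` / `skew_regression()` / `skew_distribution()` /
  `radial_histogram()` / `sidechain_shape_stats()`** — diagnostics that
  quantify the straight-axis, constant-width and sidechain-sphere
  approximations.
- **`generate_ideal_helix()` / `generate_charged_pair()`** — seeded ideal
  helices and charged toy bundles with known geometry, so the whole pipeline
  runs and is testable with no external data.
- **`run_model()` / `run_force()` / `run_diagnose()` / `run_synth()`** — file
  in, files out pipeline entry points; a thin CLI wrapper lives in
  `inst/cli/helixforce.R`.

## Worked example

A synthetic two-helix bundle whose single +1/−1 sidechain pair sits exactly
10 Å apart:

```r
library(helixforce)

cfg <- run_config(output_dir = tempfile(), seed = 1)
paths <- run_synth(cfg, separation = 10, charges_a = c(1L), charges_b = c(-1L))
cfg$structure_path  <- paths$structure_path
cfg$annotation_path <- paths$annotation_path

models <- run_model(cfg)
attr(models, "summary")
#> # A tibble: 2 × 4
#>   helix_id n_residues radius axis_length
#>      <int>      <int>  <dbl>       <dbl>
#> 1        1          4   1.88        4.91
#> 2        2          4   1.88        4.91

res <- run_force(cfg)
res
#> <bundle_force_result> bundle: net static force -231 pN (attractive) over 1 charge pairs
tidy(res)[, c("residue_a", "residue_b", "charge_a", "charge_b", "distance", "force")]
#> # A tibble: 1 × 6
#>   residue_a residue_b charge_a charge_b distance force
#>       <int>     <int>    <int>    <int>    <dbl> <dbl>
#> 1         1         1        1       -1       10 -231.
```

The −231 pN (−230.707755… exactly) is the closed-form Coulomb force of unit
charges 1 nm apart in vacuum — the end-to-end pipeline reproduces it through
the PDB writer, parser, geometry fit, frame placement and charge assignment.
The 1.88 Å radius (rather than the 2.3 Å construction radius) is the
expected principal-axis tilt of a 4-residue helix; see the methods vignette.

Diagnostics on a set of noisy ideal helices:

```r
ms <- lapply(1:10, function(s) {
  gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 36L,
                                               jitter_sd = 0.2, seed = s))
  build_helix_model(group_residues(gen$atoms, gen$annotation), helix_id = s)
})
skew_distribution(ms)
#> <skew_distribution> 10 helices: median 0.0517 deg, mean 0.0526 deg, sd 0.0789 deg
radial_histogram(ms)$mean
#> [1] 2.300034
```

Sub-0.1° skew angles mean the fitted width is constant along the helices, as
constructed; the pooled radius recovers the 2.3 Å ground truth. For real
bundles, point `run_config()` at a PDB file and an annotation CSV
(`helix_id,chain_id,start_seq,end_seq`, inclusive PDB residue numbers) and
run the same three commands.

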