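---
title: "Quantifying transmembrane-helix bending and its structural consequences in claudins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transmembrane-helix bending and its structural consequences in claudins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldngeom)
```

## The scientific question

Claudins are tetraspan membrane proteins whose side-by-side (cis) and
head-to-head (trans) interactions polymerize into tight-junction strands.
Across the family, the residue at the base of the extracellular segment of
the third transmembrane helix (TM3) — proline, glycine, or alanine
depending on subtype — decides whether TM3 is bent or straight. Because
the extracellular domain (ECD) hangs off the top of TM3, a kink of a few
degrees at this "thenar" position levers the whole ECD by several
Ångström, repositioning the residues that form the cis-interaction pocket
and thereby changing strand morphology.

`cldngeom` turns that comparison into a reproducible computation. Its
stages are: (i) a vertex-anchored bend angle for a helix; (ii) rigid
superposition of two structures via an iteratively selected low-RMSD core
with a per-residue displacement profile; (iii) a membrane frame estimated
from the four-helix bundle, used to measure the vertical aperture of the
cis-interaction pocket; (iv) within-crystal B-factor comparison between
the two molecule copies of an asymmetric unit; (v) one-site saturation
binding fits for FSEC-style titrations; and (vi) alignment-column
composition at the thenar position. A synthetic-structure generator
provides fixtures with known ground truth, so every stage is validated by
parameter recovery with no external downloads.

## The bend angle

A bend measurement is anchored at a vertex residue `v` with two flanking
arms (residue intervals that exclude `v`). Each arm's axis is a total
least-squares line; the bend is

$$\theta = \arccos(\hat{d}_\text{prox} \cdot \hat{d}_\text{dist}),$$

with both directions oriented N→C, so a straight helix reads ≈ 0° and
θ is the deviation from collinearity. For claudin-3 numbering the
defaults are vertex 134, proximal arm 118–133, distal arm 135–149. The
distal arm is the "thumb" segment of TM3 that protrudes from the
membrane; the proximal arm is the membrane-embedded part of TM3 ending
just below the vertex. Deposited claudin structures do not state the arm
ranges used for their printed angles, so these are declared package
defaults, exposed in the configuration.

**Why the fit uses an axis trace.** The principal axis of raw Cα
coordinates of a *short* helical segment is biased by the spiral phase:
for ~15-residue arms the bias reaches ~2°, which would swamp a
sub-degree recovery requirement. `bend_angle()` therefore fits the line
to the helix *axis trace* — the running mean of Cα positions over a
4-residue window (≈ one α-helical turn, 3.6 residues), which cancels
most of the circular component. This is still a single total
least-squares line per arm, not a local-axis method. With this choice
the constructed-kink recovery error is ≤ 0.3° noiselessly across kinks
of 0–60° (34-residue helix, vertex 17), and ≤ 2° for 95% of seeds at
0.3 Å isotropic Cα noise — the tolerances asserted by the test suite.
`fit_axis()` itself keeps the plain principal-component contract (raw
points in, principal eigenvector out) for callers that want it.

Angles from different structures are compared as simple differences
(`bend_difference()`, convention: bent form minus straight form) and
averaged over the molecule copies in the asymmetric unit (`mean_bend()`),
because a crystal typically contains two copies whose angles differ by
crystal-packing noise.

## Superposition and displacement profiling

`kabsch()` is the closed-form least-squares superposition restricted to
proper rotations (the smallest singular direction is sign-corrected, so
mirrored inputs are never "solved" with a reflection). Degenerate
collinear inputs are accepted; any minimizing proper rotation is
returned and the RMSD is still exact.

`core_superpose()` implements the "low-RMSD region" idea: starting from
an initial core (default: the transmembrane rigid segments 1–27, 78–133,
160–200, which exclude the mobile distal TM3 arm and the ECD), it
iterates fit → per-residue deviation → reject residues above the
threshold (default 2.0 Å, a conventional low-RMSD-core cutoff; an
adaptive mode uses 2× the current core RMSD) until stable. The core may
not shrink below 20% of its initial size (floor 3 residues); that is
reported as non-convergence with the size trace rather than silently
returning a tiny core. Correspondence is by author residue number, which
is exact for point mutants of one protein; cross-subtype superposition
via sequence alignment is deliberately out of scope.

`displacement_profile()` then reports |Cα_A − T(Cα_B)| per residue. For
a hinge-like difference (a kink at the TM3 vertex) the displacement
grows with distance from the hinge axis; on the synthetic claudin-like
pair below, the extracellular edge reaches the constructed maximum of
5 Å. Displacements are Cα-level; crystallographic figures sometimes
annotate side-chain distances, which will differ for long side chains.

## Membrane frame and pocket aperture

There is no lipid in a crystal structure, so "perpendicular to the
membrane" must be derived from the protein itself.
`estimate_membrane_normal()` fits an axis to each transmembrane helix
(defaults TM1 8–27, TM2 78–98, TM3 118–149, TM4 160–182 — engineering
defaults, config-exposed), orients each cytosolic→extracellular using
the tetraspan topology (TM1, TM3 run in→out; TM2, TM4 out→in and are
flipped), and averages. If the oriented axes nearly cancel (mean vector
norm < 0.5) the topology is inconsistent with the model and an error is
raised rather than returning a meaningless frame.

`pocket_vertical_width()` projects the side-chain heavy-atom centroid
of each rim residue onto the normal and reports (mean upper) − (mean
lower). Defaults are the claudin-3 rims: Phe146/Tyr147 on the
extracellular edge of TM3 (upper) and Glu158/Met159 on β5 (lower). The
centroid was chosen over Cβ or ring-tip atoms because it is robust at
the 3.5–4 Å resolutions typical of membrane-protein crystals and
symmetric across residue types; glycine (and Cα-only synthetic models)
falls back to Cα. The width is reported signed so rim inversion is
detectable; the absolute value is also included. Because the upper rim
rides on the distal TM3 arm, the width decreases monotonically with the
kink on hinge-constructed fixtures — the inequality (bent narrower than
straight) is the scientifically meaningful output; deposited structures
print no Å value for it.

## B-factor chain comparison

`chain_bfactor_profile()` averages isotropic B per residue over backbone
atoms (N, CA, C, O) by default — side-chain disorder dominates all-atom
averages at modest resolution. `compare_chains()` differences the
profiles over shared residues and summarizes the mean delta and the
fraction of residues where the second chain is higher (ties count 0.5,
so identical chains score exactly 0.5). Comparisons are only made within
one model (one crystal); B-factors are not normalized across crystals,
because refinement protocol and resolution differences make cross-crystal
magnitudes incommensurable. The recoverable ground truth in testing is a
constructed per-chain offset: a 20 Å² offset with 1 Å² jitter is
recovered within 2 Å².

## Binding curves

FSEC titrations report bound and unbound peak heights at each ligand
concentration. The raw fraction is taken as bound/(bound + unbound); the
phrase "normalizing the bound peak by the unbound peak" is ambiguous, so
the plain ratio bound/unbound is available behind `mode = "ratio"`. The
series is then rescaled so the saturating point (defaulting to the
highest concentration, e.g. 1 μM in a 0–1 μM titration) equals 1, and
clipped to [0, 1]. `fit_one_site()` fits

$$f(L) = \frac{B_\text{max}\, L}{K_d + L}$$

by nonlinear least squares on untransformed fractions (no Scatchard
linearization), multistarted over log-spaced initial Kd values.
B_max is fixed at 1 in normalized mode because the anchor defines the
maximum; a free-B_max mode exists for sensitivity checks. Data that do
not bracket half-saturation (no point below 0.8 and none above 0.2) are
rejected as unidentifiable instead of returning an unconstrained Kd.
`compare_affinity()` reports Kd ratios with a residual-resampling
bootstrap percentile interval. Note that anchoring at a finite
concentration biases fractions upward by the factor (Kd + L_sat)/L_sat;
for Kd = 0.05 μM anchored at 1 μM this is ≈ 5%, visible as a small
downward Kd bias when fitting anchored data — a property of the assay's
normalization, not of the fit.

## The synthetic generators

`make_ideal_helix()` places Cα atoms on a regular helix (defaults: rise
1.5 Å/residue, twist 100°/residue, radius 2.3 Å — canonical α-helix
values). `make_kinked_helix()` rotates the ideal continuation past a
vertex by exactly the kink angle about an axis perpendicular to the
helix axis through the vertex Cα — continuity is automatic and the
constructed angle is the recovery oracle. `make_domain_pair()` builds
two-model pairs whose mobile domain differs by a known rigid transform
(plus optional isotropic Gaussian noise, seeded), the oracle for core
selection and displacement profiling. `make_helix_bundle()` packs
alternating-direction helices with known analytic mean axis.
`assign_bfactors()` writes B = base + chain offset + z-gradient +
jitter, clamped at zero.

`make_claudin_like()` composes these into a one-chain claudin-style
molecule in author numbering: four-helix bundle, TM3 kinked at residue
134, an extracellular "sheet" (residues 28–77) hinged on the distal TM3
arm whose farthest point sits ≈ 36 Å from the hinge — so an 8° kink
difference moves it by 2·sin(4°)·36 ≈ 5 Å, the geometric regime of a
claudin ECD — and the two pocket rims (146/147 moving, 158/159 static).
The bent/straight study pair uses kinks of 25° and 17°: the bent-form
angle, the straight-form angle (which is non-zero — a "straight" TM3
still reads a substantial deviation-from-collinearity because the
measurement is unsigned), and their 8° difference.

What the generator does **not** emulate: side chains and rotamers,
irregular helix geometry (π-bulges, 3₁₀ segments), real β-sheet
topology, correlated/anisotropic displacement, crystal packing, and
solvent. Passing recovery tests therefore demonstrate the correctness of
the measurements under their geometric assumptions, not robustness to
every pathology of real electron-density-derived models. Running the
pipeline on deposited coordinate files is supported end to end
(`analysis_config()` + `run_report()` accept any local PDB/mmCIF paths,
and the claudin-3 residue conventions are the defaults); those files are
a few-MB download from the public archive and are not redistributed with
the package.

## Numerical choices and degenerate inputs

* Altloc policy: highest occupancy wins, ties break lexicographically —
  deterministic and order-independent.
* Insertion codes are carried by the data model but rejected inside
  geometry ranges (claudin numbering has none; silently collapsing them
  would corrupt correspondences).
* Hydrogens and waters are ignored in all geometry; only the first
  model of a multi-model file is read.
* Arm/TM axis fits require ≥ 5 Cα and ≥ 80% range coverage; missing
  residues are named in the error.
* `kabsch()` requires ≥ 3 points; collinear input is handled with the
  documented any-minimizer tie-break.
* Angles are clamped into [−1, 1] before `acos` to avoid NaN at
  numerical collinearity.
* All stochastic operations take explicit integer seeds; generators are
  bit-reproducible given the seed.

## Problem sizes used by the tests and acceptance script

Kink recovery sweeps 13 angles (0–60°) noiselessly and 100 seeds per
angle at three representative angles for the noisy band; the binding
study uses 200 replicates at noise sd 0.03; the bootstrap uses 100–500
draws; the brute-force rotation-grid oracle uses a 6° Euler grid on
5-point instances. These sizes give stable estimates of the recovery
errors while keeping the whole suite fast on a single CPU.

## Known limitations

* Correspondence by residue number restricts pairwise comparison to
  structures of the same protein (mutants); no alignment-based mapping.
* The bend angle needs a user-specified vertex; there is no automatic
  kink-position scan.
* The membrane frame is a bundle-axis average, not an implicit-membrane
  optimization; for strongly tilted bundles the two can differ by a few
  degrees.
* Pocket metrics use side-chain centroids; on Cα-only models they fall
  back to Cα, which changes the absolute width (but not inequalities
  between forms measured the same way).
* B-factor comparisons are within-crystal only, by design.

## A worked end-to-end run

```{r, eval = FALSE}
dir <- tempfile()
files <- make_fixtures("kinked_pair",
                       parameters = list(theta_a = 25, theta_b = 17),
                       seed = 1, out_dir = dir)
cfg <- analysis_config(structures = c(bent = files$a, straight = files$b))
rep <- run_report(cfg)
rep$structures$bent$bend$mean_angle_deg        # ~25
rep$structures$straight$bend$mean_angle_deg    # ~17
rep$pairs$bent_vs_straight$bend_difference_deg # ~8
rep$pairs$bent_vs_straight$superposition$max_ecd_shift_A  # ~5
```

The numbered scripts under `analysis/` run the same stages with
narrative output and write their tables under `results/`.
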