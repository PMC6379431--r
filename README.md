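# cldngeom

Geometric comparison of claudin-family transmembrane structures in R.

## The problem

Claudins polymerize into tight-junction strands through side-by-side
(cis) and head-to-head (trans) interactions. A single residue at the
base of the extracellular part of the third transmembrane helix (TM3) —
proline, glycine, or alanine depending on subtype — controls whether TM3
is bent or straight. Because the extracellular domain (ECD) hangs off
TM3, a bend of a few degrees at this position levers the ECD by several
Ångström and reshapes the cis-interaction pocket, which correlates with
tight-junction strand morphology. Comparing a bent and a straight form
quantitatively requires a set of careful geometric measurements that
this package implements as tested, reusable functions:

* **Vertex-anchored bend angle** — the deviation from collinearity
  `θ = arccos(d̂_prox · d̂_dist)` between total-least-squares axes fitted
  to the helix arms on either side of a designated vertex residue (the
  arms are fitted on a one-turn running-mean axis trace, which keeps
  short-arm fits unbiased to ≈ 0.3°).
* **Low-RMSD-core superposition** — closed-form Kabsch fit (proper
  rotations only) with iterative rejection of residues deviating more
  than a threshold (default 2 Å), plus per-residue Cα displacement
  profiles of the regions outside the core.
* **Membrane-frame pocket aperture** — the membrane normal estimated
  from the four TM helix axes (topology-oriented average) and the
  vertical width of the cis-interaction pocket as the difference of
  side-chain-centroid projections of its upper (146/147) and lower
  (158/159) rims onto that normal.
* **B-factor chain comparison** — per-residue backbone B-factor
  profiles and the mean chain-to-chain difference within one asymmetric
  unit.
* **One-site binding fits** — FSEC peak-height normalization to
  fraction bound and nonlinear least-squares fitting of
  `f(L) = L/(Kd + L)`, with bootstrap affinity ratios.
* **Alignment-column composition** — amino-acid frequencies at the
  alignment column of a reference residue (the family-conservation view
  of the helix-breaking position).

Every stage has a synthetic-structure generator twin with known ground
truth (kink angle, rigid displacement, bundle axis, B-factor offset,
Kd), so the whole pipeline is validated by parameter recovery without
downloading anything.

## Worked example

```r
library(cldngeom)

dir <- tempfile()
files <- make_fixtures("kinked_pair",
                       parameters = list(theta_a = 25, theta_b = 17),
                       seed = 1, out_dir = dir)
cfg <- analysis_config(structures = c(bent = files$a, straight = files$b))
rep <- run_report(cfg)

rep$structures$bent$bend$mean_angle_deg
#> [1] 24.88995
rep$structures$straight$bend$mean_angle_deg
#> [1] 16.88858
rep$pairs$bent_vs_straight$bend_difference_deg
#> [1] 8.001374
rep$pairs$bent_vs_straight$superposition$max_ecd_shift_A
#> [1] 5.001028
rep$structures$bent$pocket$A$vertical_width_A     # bent pocket ...
#> [1] 5.800957
rep$structures$straight$pocket$A$vertical_width_A # ... is narrower
#> [1] 7.023914
```

Reading: the bent form's TM3 bends ≈ 25° at the vertex residue and the
straight form ≈ 17°, so the helix-breaking residue accounts for ≈ 8° of
bend; after superposing the two models on their rigid transmembrane
core, the extracellular domain shifts by up to ≈ 5 Å; and the
cis-interaction pocket of the bent form is vertically narrower than the
straight form's. To analyse deposited crystal structures instead, point
`analysis_config(structures = ...)` at local PDB/mmCIF files — the
claudin-3 residue conventions (vertex 134, arms 118–133/135–149, core
1–27 + 78–133 + 160–200, rims 146–147/158–159) are the defaults.

The numbered scripts under `analysis/` run each stage with narrative
output (fixture generation, bend-angle recovery, superposition and
displacement, pocket-width sweep, B-factor comparison, binding fits,
full report) and write their tables under `results/`.

## Package layout

* `R/` — the implementation (structure I/O, synthetic generators, helix
  geometry, superposition, membrane/pocket, B-factors, binding, MSA
  composition, pipeline).
* `analysis/` — numbered narrative drivers over the package functions.
* `tests/testthat/` — parameter-recovery and property tests, all on
  generated fixtures.
* `vignettes/claudin-tm3-geometry.Rmd` — the methods write-up: models,
  defaults, numerical choices, limitations.
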