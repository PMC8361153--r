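# serialface

Superimposition and distance analysis of serial 3D facial surfaces in
growing individuals.

## The problem

Facial change over time — growth, treatment effects, weight change — can be
measured from serial 3D facial surfaces (stereophotogrammetry or
CBCT-derived), but only after the two surfaces are rigidly aligned on a
*reference area* that is itself morphologically stable. If the chosen
reference deforms between the two scans, a best-fit registration averages
that deformation into the pose and corrupts every downstream measurement.
This package implements the full assessment workflow for candidate
reference areas, for researchers in orthodontics, maxillofacial surgery and
craniofacial biology:

* **Region-constrained rigid superimposition** of T1 onto T0 by
  point-to-plane ICP: exact closest-point-on-surface correspondences,
  overhang (boundary) exclusion, 100% sampling, closed-form 6×6
  point-to-plane steps with exact (Rodrigues) rotations, up to 50 inner
  iterations, and an outer repeat-until-minimum-distance loop. The core
  objective per step is
  `min Σ [ nᵢ · (R sᵢ + t − cᵢ) ]²` over rigid `(R, t)`.
* **Five anatomical reference areas** (whole face minus eyes/mouth/nose
  tip; forehead + nasal base; upper half-face; forehead rectangle +
  mid-nose + infraorbital; the latter without the forehead) built
  parametrically from 16 soft-tissue landmarks in a reproducible face
  frame, plus seven 100-vertex measurement patches seeded at soft nasion,
  soft A-point, soft pogonion, zygia and gonia.
* **Signed point-to-surface distance maps** (anterior change positive),
  per-patch mean absolute distances (MAD), method-vs-gold-standard T1
  placement differences, reference-area congruence, reproducibility
  differences, and colour-coded PLY export.
* **Nonparametric statistics**: Kruskal–Wallis omnibus, Dunn–Bonferroni
  post hoc, Shapiro–Wilk / Lilliefors-KS normality screening, two-sided at
  α = 0.05.
* **A synthetic longitudinal face generator** with closed-form landmarks,
  parameterized growth fields (lower-face protrusion, global forward
  drift, nasal growth, cheek adiposity), correlated acquisition noise and
  a known rigid misalignment — so the gold-standard alignment is available
  by construction and every claim is testable against ground truth.

## Worked example

```r
library(serialface)

co <- generate_cohort(2, "stable", seed = 1)   # 18 in the full study
s  <- co$subjects[[1]]
s
#> synthetic_subject S01 - 2995 vertices; protrusion 1.631727 mm, drift 0 mm

res <- superimpose_subject(s, "area4")         # point-to-plane ICP on area 4
res
#> superimposition_result: 2 outer run(s), 6 inner iterations,
#> final residual 0.04006 mm, converged

d <- method_gold_disagreement(s, res$transform)
sprintf("%.3f mm mean, %.4f deg rotation", d$mean_displacement_mm,
        d$rotation_error_deg)
#> "0.375 mm mean, 0.4398 deg rotation"

subject_change_report(s, res$transform)$report
#>       patch     mad_mm n_vertices
#> 1    meas_N 0.05623674        100
#> 2    meas_A 0.14726008        100
#> 3  meas_Pog 1.55423702        100
#> 4 meas_ZygR 0.08653556        100
#> 5 meas_ZygL 0.16167310        100
#> 6  meas_GoR 1.56431018        100
#> 7  meas_GoL 1.32664135        100
```

Reading the output: this subject's simulated growth is a 1.63 mm lower-face
protrusion with a random scan misalignment. The area-4 ICP converges after
two outer runs; its placement differs from the ground-truth gold placement
by 0.375 mm mean vertex displacement (the pose uncertainty induced by
0.05 mm correlated surface noise on a small reference area). The per-patch
T0–T1 MADs then read the imposed growth where it happened — ~1.3–1.6 mm at
pogonion and both gonial patches (protrusion weight ≈ 1 there) and near
zero at nasion, A-point and the zygia.

The numbered scripts under `analysis/` run the full study: cohort
simulation, registration validation, reference-area comparison against the
gold standard (per-patch difference sums, Kruskal–Wallis/Dunn statistics),
directional-bias quantification, and repeated-run reproducibility. Each
prints its findings and writes tables under `results/`.

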