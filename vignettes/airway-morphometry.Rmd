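---
title: "Upper-airway morphometry and symbolic-regression modelling: methods"
author: "airwaymorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upper-airway morphometry and symbolic-regression modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The problem

Cone-beam CT of the craniofacial region gives access both to a 3D
segmentation of the upper airway (from the hard palate down to the third
cervical vertebra) and to the positions of classical hard- and soft-tissue
anatomical landmarks. Clinically, a narrow airway — small volume, small
minimal axial cross-section — is a marker of risk for obstructive sleep
apnea, and the question this package operationalizes is: *which simple
anatomical measures carry information about airway size?*

The pipeline is: reorient each subject to a standard anatomical frame,
compute a panel of 25 cephalometric measures from 25 named landmarks,
extract airway volume (`Vol`, mm³) and the minimal axial cross-sectional
area (`CSAmin`, mm², with its anteroposterior `Ap` and lateral `Lat`
extents) from a binary voxel grid, describe and correlate everything, and
finally model `Vol` and `CSAmin` by genetic-programming symbolic
regression, summarizing each predictor's role by a normalized
fitness-weighted importance and a signed sensitivity magnitude.

Because clinical CBCT data cannot be redistributed, the package ships a
synthetic-cohort generator with a *planted*, analytically known effect
structure; every downstream stage is validated against that ground truth.

## Reorientation

Two anatomical planes define the standard frame:

* the **Frankfort horizontal plane**, fit through the right porion (rPo)
  and both infraorbital points (rOr, lOr), is made horizontal, normal
  pointing superiorly;
* the **midsagittal plane**, through nasion (Na), the anterior nasal
  spine (ANS) and the mid-posterior point of the foramen magnum (MGNM),
  is then aligned by an in-plane rotation about the vertical axis, so the
  Frankfort alignment is never disturbed.

The two steps are applied in this order because the second rotation is
constrained to the horizontal component of the midsagittal normal: after
the Frankfort step the three midsagittal landmarks need not be exactly
coplanar with any vertical plane, so only that horizontal component is
meaningful, and the residual |y| of Na, ANS and MGNM is reported as a QC
metric on the returned transform. The axes are +X anterior (from MGNM
toward Na), +Y subject-left, +Z superior; the origin is placed at the
sella (S). The origin choice is arbitrary — every measure is either a
Euclidean invariant or a coordinate difference — but fixing it makes
transforms comparable across subjects. Rotations are always proper
(determinant +1); reflections are rejected at construction.

Degenerate inputs fail loudly: collinear plane-defining points (triangle
area below 10⁻⁶ mm²) and reference planes within 10° of parallel are
errors, not warnings.

## The measurement panel

The 19 distances and 6 angles are computed from the reoriented landmark
set: plain Euclidean distances (e.g. `S_Na`, `C3_H`, `BEP_A`), vertex
angles in degrees (`SNA`, `SNB`, the facial angle, `H_S_Ba`, `H_Na_S`),
and four frame-dependent constructions:

* `AB_shift` — the **signed** anteroposterior component x(A) − x(B) of
  the Frankfort-plane projections. It is signed (not an unsigned 2D
  distance) because a protrusive mandible must be representable as a
  negative shift; published adult tables include negative minima.
* `HSP` — |x(PNS) − x(LP)|, the horizontal offset between the posterior
  nasal spine and the most posterior soft-palate contour point. `LP` is
  an explicit 25th landmark: the package consumes landmark tables, not
  gray-level images, so "most posterior contour" must be annotated.
* `VSP` — |z(PNS) − z(TUV)|, the vertical drop from the palatal plane to
  the uvula tip. The "tip of the soft palate" is mapped to the uvula-tip
  landmark TUV; the full Euclidean `PNS_TUV` is kept as a separate
  measure.
* `FMA` — the angle between the Frankfort line (rPo–rOr) and the
  mandibular line (Me–rGo) after projecting both onto the sagittal XZ
  plane, reported in (0°, 90°], matching how the angle is read on a
  lateral view.

A missing landmark either raises an error naming the absent point
(mirroring the usual exam non-inclusion rule) or, in degraded mode,
returns `NA` for the affected measures; the pipeline then excludes those
columns from statistics and modelling with a warning.

## Airway extraction

The airway is a binary voxel grid (air = 1) on an isotropic lattice in
the reoriented frame. The superior boundary is the axial plane through
the hard palate: since PNS and ANS rarely share a z-coordinate exactly,
the mean of their z-values is used and a disagreement above 3 mm emits a
warning. The inferior boundary is the axial plane through C3. Cropping
keeps voxels whose centers fall in [z(C3), z(palate)], both ends
inclusive. Per axial slice, area = air-voxel count × voxel²; `CSAmin` is
the minimum over non-empty slices, ties resolved toward the most inferior
slice; `Ap`/`Lat` are the bounding-box extents of air voxels in that
slice (center-to-center plus one voxel). A single 26-connected
largest-component filter can be applied in 3D before slicing to drop
stray voxels, emulating segmentation of one airway object. Maximal-chord
definitions of `Ap`/`Lat` would also be defensible; the bounding box was
chosen and is documented because it matches "width in a coronal view /
length in a sagittal view" as linear dimensions.

## The synthetic cohort

The generator starts from a hand-built template: 25 landmark positions in
the canonical frame whose measure vector falls inside published
normal-adult ranges, with the four major cephalometric angles constructed
exactly (SNA 81.8°, SNB 77.8°, facial angle 79.0°, FMA 33.3°). Per
subject:

1. every landmark is jittered by isotropic Gaussian noise
   (`landmark_sd`, default 3 mm per axis) — this is the *only* source of
   between-subject shape variation, which keeps all ground truth
   analytic;
2. the jittered set is reoriented and its true measure vector recorded;
3. airway volume is drawn from the planted linear model
   `Vol = β₀ − 1000·HSP + 350·BEP_A + 250·Na_B + ε`, with β₀ anchored so
   the expected volume at the template is 14,460 mm³ and
   `ε ~ N(0, 5800²)` chosen so the total SD is ≈ 7,400 mm³. The dominant,
   negative soft-palate coefficient makes a longer horizontal soft palate
   shrink the airway — the qualitative relationship the modelling stage
   must recover — and yields a Kendall τ between `Vol` and `HSP` of about
   −0.3, the strength reported for adult cohorts;
4. `CSAmin` is planted *through the waist ratio*
   `u = CSAmin·height/Vol`, drawn as `0.88 − 0.01·(HSP − 19.1) + N(0, 0.06²)`
   and clamped to (0.30, 0.95). Any tube between two planes satisfies
   `Vol ≥ CSAmin·height`, so an independent linear draw for `CSAmin`
   would frequently be geometrically impossible; tying it to `Vol` keeps
   every subject realizable while preserving a monotone negative
   dependence on `HSP` and a mean ≈ 206 mm², SD ≈ 110 mm²;
5. a uniform random rigid pose (±20° per axis, ±30 mm) produces the
   raw-frame landmarks — large enough to exercise reorientation, small
   enough to avoid gimbal-degenerate poses;
6. age ~ N(39.5, 13.5²) truncated to [22, 72] and sex ~ Bernoulli(0.70
   female) are passed through as covariates.

Airway grids are analytic tubes with elliptical cross-section (lateral to
anteroposterior aspect 2.6, matching reported `Lat`/`Ap` proportions) and
a cosine-modulated area profile with a single interior minimum at
mid-height, so the minimal slice always lies strictly between the
bounding planes and `A_max = 2·Vol/height − CSAmin` makes the integral
exact. Voxelization is area-matched: each slice fills the
`round(A(z)/voxel²)` cells closest to the tube axis in the elliptical
metric, which bounds every slice-area error by half a voxel footprint and
makes the discretization error decrease under voxel halving — naive
center-in-ellipse counting does not converge monotonically (lattice
alignment can freeze the error across refinements, as happens for a
radius-10-voxel circle).

What the generator does **not** emulate: correlated anatomical covariance
beyond the planted model (real measures co-vary through growth patterns),
soft-tissue deformation, scanner gray levels and artifacts, and
non-elliptical airway lumina. Passing tests therefore demonstrate that
the *pipeline* recovers known structure from geometrically realistic
inputs — not that the planted model is a faithful generative model of
human anatomy.

## Classical statistics

* **Descriptives** report mean, SD, median, quartiles, min/max, plus a
  Shapiro–Wilk flag (delegated to `stats::shapiro.test`); quartiles are
  first-class because airway measures are typically non-normal.
* **Kendall τ-b** is computed by pair enumeration with the tie-corrected
  denominator, and p-values from the tie-corrected normal approximation
  of the concordance score. Significance is per-pair at α = 0.05 by
  default — matching the usual reporting convention — with an optional
  Benjamini–Hochberg adjustment that is off by default.
* **ICC** is the two-way mixed-effects, absolute-agreement,
  single-measurement form ICC(A,1) — the recommended choice for
  intra-rater reliability with a fixed rater — estimated from the two-way
  ANOVA mean squares with the F-based McGraw–Wong 95% interval
  (Satterthwaite degrees of freedom). Identical sessions return exactly 1
  with a collapsed interval; zero total variance is an error; fewer than
  5 subjects is an error because the interval is unstable.
* **PCA** standardizes variables and eigen-decomposes the correlation
  matrix; variable coordinates are loadings scaled by √eigenvalue (their
  correlations with the components, as drawn on a correlation circle),
  with cos² as quality of representation.

## Symbolic regression

The engine is steady-state genetic programming over expression trees with
building blocks +, −, ×, ÷, exp, natural log, power and square root.
Fitness is the mean absolute error on the training rows; any non-finite
prediction on any row (division by zero, log of a non-positive value,
square root of a negative, invalid power) marks a model infeasible
outright — protected operators were deliberately avoided because they
produce pathological artifacts that distort variable importance. Power
exponents are generated in [−3, 3] and capped at magnitude 10; overflow
still yields infeasibility.

Design choices that were genuinely open:

* **Linear scaling.** Each candidate structure f is scored by the MAE of
  its least-squares affine calibration a + b·f(x), and (a, b) are folded
  into the reported expression as explicit constants. Airway volumes live
  at 10⁴ mm³ while random constants are drawn at the scale of the data;
  without scaling, the search abuses transcendental compositions of
  large-valued predictors (e.g. exp(√·)) as scale anchors and the
  importance ranking reflects that artifact rather than predictive value.
  Commercial engines solve this with aggressive constant optimization;
  linear scaling is the standard desk-scale equivalent.
* **Parsimony and bloat.** Selection and replacement are tournaments
  (size 3) with lexicographic parsimony — fitness first, node count on
  ties — plus a hard cap of 30 nodes and elitism on the single best
  individual.
* **Complexity** is the plain node count of the reported expression with
  unit operator weights: the simplest defensible Pareto axis.
* **The Pareto archive** keeps, for each reported complexity, the best
  training MAE seen during the whole run, and the returned front is the
  strictly-improving envelope (larger models must fit strictly better).
  The mean predictor is always seeded at complexity 1 as the baseline.
  Remaining front models get a final Nelder–Mead polish of their
  constants (training MAE objective) before validation scoring.
* **Best model of a run** = lowest validation MAE on the front, ties
  toward lower complexity. "Best" is not defined by the original
  Eureqa-style workflow; this rule is the natural validation-first
  choice.
* **Budgets.** Defaults are population 500, 200 generations (one
  generation = one population of steady-state offspring, so 100,000
  evaluations per run) and 10 independent runs with fresh 80/20
  train/validation splits. Industrial runs use many orders of magnitude
  more evaluations; the recovery experiments in the test suite
  (noiseless planted linear model, 200 rows, five decoys) pass reliably
  at this desk scale, which is the calibration the defaults encode.
* **Importance** of a variable is the proportion of pooled Pareto-front
  models (all fronts of all runs) containing it, each model weighted by
  1/(10⁻¹² + validation MAE), normalized to sum to 1. The in-text
  description this implements — "proportion of equations weighted by
  their fit" — does not pin down the model set or the exact weighting;
  pooling fronts with inverse-MAE weights is the declared
  interpretation.
* **Sensitivity** (magnitude of effects) of variable j in a model f is
  the mean over rows of ∂f/∂xⱼ (central differences, step 10⁻⁴·SD(xⱼ))
  standardized by SD(xⱼ)/SD(f); the signed mean (not |∂f| with a side
  sign) is used, so +1 means "one SD in xⱼ moves f one SD up". Variables
  with undefined derivatives on more than 10% of rows are flagged. The
  mean magnitude across runs averages the best models containing the
  variable and reports the containment count.

Everything is deterministic under a fixed seed at fixed budgets;
experiment seeds are derived from the root seed.

## Numerical conventions

* plane fit residuals < 10⁻⁹ mm; reorientation round-trip agreement to
  10⁻⁶ mm is asserted in tests;
* voxel phantoms (cylinder, hourglass) at 0.3 mm voxels reproduce
  analytic volume and CSAmin within 3%, with errors decreasing under
  voxel halving;
* CSAmin slice ties go to the most inferior slice; crop bounds are
  inclusive at both planes;
* the problem sizes exercised by the test-suite experiments — 60-subject
  cohorts, 200-row recovery datasets, 10 runs × 100k evaluations — are
  the package's declared desk-scale defaults.

## Known limitations

* Landmark jitter is independent and isotropic, so measure-measure
  correlations beyond the planted model are near zero; correlation
  matrices on synthetic cohorts are sparser than on real ones.
* The waist-ratio construction couples `CSAmin` tightly to `Vol`
  (realistic in direction, but the coupling strength is an assumption).
* Ap/Lat bounding-box extents differ from maximal chords for concave
  slices; synthetic slices are elliptical, so the difference vanishes
  here but may not on real segmentations.
* The GP explores a tiny fraction of expression space compared to
  industrial engines; importance rankings below the first few variables
  are noisy at these budgets.
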