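---
title: "Methods: PET intensity-based dose painting with an arc-therapy class solution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET intensity-based dose painting with an arc-therapy class solution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dosepaint)
```

This vignette documents the models, parameters and numerical choices behind
`dosepaint`. It is the package's design record: every default stated here is
the one the code ships with, and every behavior described is exercised by
the test suite.

## 1. The planning problem

Dose painting by numbers treats the tumor as biologically heterogeneous:
regions with higher ¹⁸F-FDG uptake are assumed to need more dose. In the
adaptive workflow modelled here, a head-and-neck treatment of 30 fractions
is split into three phases of 10 fractions. Phases I and II are planned on
freshly acquired PET/CT (before treatment and after fraction 8) and paint
the primary tumor between `D_low` and `D_high` per fraction; phase III is
planned on CT only (after fraction 18) and prescribes a uniform
2 Gy/fraction to the high-risk PTV. Doses of the three plans are summed on
the pretreatment CT through deformable registrations for reporting.

## 2. Intensity-to-dose mapping

The per-fraction prescription is the clamped linear ramp implemented by
`prescribed_dose()`:

* `D_low = 2.2` Gy/fraction and `D_high = 3.1` Gy/fraction, giving
  66–82 Gy over 20 painted + 10 uniform fractions;
* `I_high` = 95% of the maximum in-target PET intensity, `I_low` = 25% of
  `I_high` (`compute_intensity_window()`). Using the 95th-percentile-style
  cap rather than the raw maximum makes the window robust to a single hot
  voxel;
* at most `1.75 cm³` of the GTV may exceed `2.9` Gy/fraction. The mapping
  itself is never modified; `audit_boost_volume()` reports the offending
  volume because the rule is an allowance, not a transform.

The mapping is monotone, continuous and bounded for *any* real intensity,
and scaling the PET image by a positive constant leaves every prescribed
dose unchanged (the window scales with the image). Both properties are
enforced by property tests.

The discrete PET grid (4 mm isotropic by default) is extended to the
continuum by trilinear interpolation. Prescription points are seeded
uniformly over the target volume by rejection sampling inside the mask
bounding box — exact uniformity on arbitrary mask shapes, at the price of
a rejection rate equal to one minus the mask's bounding-box fill fraction.
The number of points is not fixed by the protocol; the package defaults to
1500 points per painted target for optimization and 5000 for evaluation,
which makes the Monte-Carlo error of the reported QF (≈ σ/√n) a few
hundredths of a percentage point. Nodal targets with insufficient PET
signal receive a flat 2.2 Gy/fraction median prescription via the
`flat_dose` switch.

## 3. Dose engine

The engine (`deposit_dose()`, `dose_engine_config()`) is a deliberately
simple surrogate for a clinical convolution/superposition algorithm. Per
control point, dose at a point is

    calibration × MU × F(u, v) × exp(−μ_eff · depth) × (SAD/(SAD+w))²

* `F` is the aperture indicator (leaf openings ∩ jaws, collimator-rotated)
  under a Gaussian penumbra of `σ = 3 mm`, evaluated analytically with
  error functions rather than by rasterize-and-blur;
* `μ_eff = 0.005 /mm` approximates a 6 MV depth-dose slope in water;
* `depth` is the radiological path length inside the body along the beam
  direction, computed by parallel-ray marching over the binary body mask at
  `depth_step = 3 mm`;
* `calibration = 0.01 Gy/MU` for an open ray at zero depth at the
  isocenter plane; `SAD = 1000 mm`.

Assumptions and their consequences: no scatter, no buildup, no
heterogeneity correction beyond the binary body path, and parallel (not
divergent) rays for the depth integral. Absolute dose values are therefore
approximate; linearity in MU, superposition over control points and beams,
zero dose outside the body, and the central-axis closed form
`exp(−μd)·(SAD/(SAD+z))²` are exact and tested. Arc dose is a discrete sum
over control points; the control-point spacing is a parameter precisely so
the discretization effect can be studied.

The isocenter is the world origin; phantom grids are centered on it.

## 4. Machine model and aperture generation

The machine (`machine_model()`) has 40 leaf pairs of 10 mm projected
width and a minimum 1 cm opening between opposing and diagonally opposing
leaves of rows exposed by the jaws. Speed and dose-rate limits
(6°/s gantry, 25 mm/s leaf, 10°/s collimator, 0.5–10 MU/s) are assumed
typical C-arm values and only affect the delivery-time estimate, which is
a planning surrogate, not a timing model of any physical linac.

`abst_aperture()` builds anatomy-based openings: target voxel centers are
projected to the isocenter plane (divergent magnification), binned per
leaf row, widened by a 6 mm margin to compensate the penumbra, and
avoidance-structure projections are subtracted. When an avoidance splits a
row, a single leaf pair can keep only one segment; the kept side is a
parameter (`wider`, `left`, `right`) and the class solution *cycles* the
preference along the arc, so no target region is shielded from every
angle. Rows that must stay closed but lie inside the jaw-open region are
physically unable to close below the 1 cm gap; they are parked at the
aperture center and the resulting leak is accepted, as on the modelled
MLC. A repair pass settles the diagonal-gap rule by opening the violating
pair symmetrically; every emitted control point is validated.

`bbst_aperture()` adds biology: the anatomy aperture is subdivided into
nested sub-apertures by thresholding the projected PET intensity at
equally spaced levels between `I_low` and `I_high` (3 bands by default).
Arcs cycle the bands over control points; static beams carry all bands as
segments.

The default class solution is one arc around `PTV_EN` from −176° to 176°
(45 control points every 8°) and one around `PTV_HR` from 144° to −144°
(37 control points). The protocol's angle pair for the second arc is
geometrically ambiguous — 144°→−144° can mean the 72° posterior span or
the 288° span through 0°; the package uses the 288° reading, which the
45/37 control-point bookkeeping implies, and the arc list in
`class_solution_config()` lets either be configured. The six-beam
step-and-shoot comparator uses gantry 45°, 75°, 165°, 195°, 285°, 315°.

## 5. MU and leaf optimization

`optimize_plan()` alternates two moves, both accepted only on decrease of
the composite objective (targets: mean squared deviation from the point
prescriptions; OARs: one-sided quadratic excess above a dose level,
exempting the allowed hottest volume fraction):

1. **MU solve** — iterated non-negative least squares
   (`pracma::lsqnonneg`) over the target rows plus the currently violating
   OAR rows, re-selected each round (a standard dose-volume reweighting);
2. **leaf moves** — randomly sampled (control point, row, bank, direction)
   proposals of `6 mm` steps, re-evaluated through a cached
   attenuation-geometry factorization so a proposal costs one fluence
   evaluation, rejected if any machine constraint would break.

Because acceptance requires strict decrease of the *true* objective, the
objective trace is monotone non-increasing by construction, and the final
control points satisfy all machine constraints. The optimizer is
deterministic for a fixed seed. Defaults (10 outer iterations, 6 MU
rounds, 50% of CP-row pairs proposed per sweep) were chosen so a full
three-phase course on the default phantom completes in a few minutes on
one CPU; they are ordinary tuning parameters, not protocol values.

OAR penalty levels encode the protocol ceilings per fraction of a
30-fraction course: spinal-cord PRV 50 Gy and brainstem PRV 60 Gy to
< 5% of the volume, mandible 70 Gy, parotids 27 Gy to half the gland, and
a soft 45 Gy median-level constraint on the swallowing structures.

## 6. Delivery post-processing

* `prune_low_mu()` removes control points below 2 MU; maximal surviving
  runs become sub-arcs.
* `refine_control_points()` subdivides any segment whose MU (> 4), gantry
  (> 2°), collimator (> 2°), leaf (> 5 mm) or jaw (> 5 mm) delta exceeds
  its limit, splitting the segment MU equally; total MU is conserved. The
  limits are configurable — the protocol states none. Interpolating
  between a parked and an open leaf row can undercut the 1 cm gap while
  the interpolated jaws expose the row, so interpolated control points are
  gap-repaired. Static beams only split MU over identical apertures (the
  beam is off between segments), leaving their dose exactly unchanged.
* `link_subarcs()` orders and orients the sub-arcs to minimize the
  estimated delivery time: exhaustively over all signed permutations up to
  6 sub-arcs (6!·2⁶ = 46 080 candidates), greedily by nearest endpoint
  above, never worse than the input ordering.
* `estimate_delivery_time()` sums per segment the limiting ratio of MU,
  gantry, leaf and collimator travel against their maxima.

## 7. Deformable accumulation

Deformation fields live on the reference grid and point *into* the phase
image (pull-back convention), which is exactly the direction needed to
resample phase dose onto the pretreatment grid with one trilinear lookup
per voxel and no scattered-data pushing. Out-of-domain samples return zero
and are counted. Plain interpolating dose mapping is used — no
energy/mass-conserving correction and no Jacobian or inverse-consistency
checks; warped values are bounded by the source range by trilinear
convexity. Summation is an elementwise scaled sum, 10 fractions per phase
by default.

## 8. Evaluation

* **Quality factor.** The protocol defines QF as the "mean deviation
  between prescribed and planned dose" without a formula; this package
  uses the mean *relative* absolute deviation (per-point |Δ|/prescribed,
  in %), the only form that makes the 5% goal dimensionless. An
  absolute-Gy variant sits behind `normalization = "absolute"`. The
  averaging set is the seeded point set by default; passing points seeded
  at PET voxel centers recovers the per-voxel reading.
* **DVH.** Exact voxel counting; `dose_at_volume()` uses the empirical
  quantile, so `D2% ≥ D50% ≥ D98%` always.
* **Gamma.** Global 3%/3mm, normalized to the prescribed dose, low-dose
  cutoff 20% (configurable; the protocol states none). The minimization is
  exhaustive over a cubic candidate set of radius 3× the distance
  tolerance at 0.5 mm steps, organized in radius shells with per-point
  early termination once the distance term alone exceeds the current
  minimum — algebraically identical to the full search, and verified
  against it. A point passes at γ ≤ 1 (+1e−9 for floating-point
  round-off; the γ < 1 vs γ ≤ 1 distinction has measure zero for
  continuous fields). Denser candidate grids can only lower γ
  (minimization over a superset) — a tested monotonicity.
* **Detector sampling.** The emulated biplanar diode array keeps the
  published facts — 1069 diodes on two orthogonal planes, 5 mm spacing in
  the central 6×6 cm, 10 mm outside — and resolves the unpublished board
  outline by filling candidate grid positions outward by radius with a
  deterministic tie-break until exactly 1069 diodes are placed.
* **Statistics.** Two-sided Wilcoxon matched-pair signed-rank test: zeros
  dropped (Wilcoxon's method; Pratt variant switchable), mid-ranks for
  ties, exact conditional enumeration by convolution up to n = 15,
  continuity-corrected normal approximation with tie correction above.
  The approximation's relative error diverges in the far tail (exact p
  can reach 2⁻¹⁵), so the exact branch is authoritative wherever it
  applies. Report tables round half away from zero to 1 decimal, the
  convention of the benchmark tables.

## 9. The synthetic phantom

`generate_phantom()` builds a schematic neck cross-section on a 64³ CT
grid at 3 mm (PET 48³ at 4 mm): an elliptic-cylinder body (80×75 mm
semi-axes), airway, vertebral column and spinal cord, brainstem, mandible
arc, two parotids, a swallowing-structure ring, a lateralized ellipsoidal
primary tumor (≈ 17 cm³) and optionally lymph nodes. Structure derivation
follows the clinical recipes: GTV + 10 mm → CTV_HR adjusted off air and
uninvolved bone by set subtraction (the adjustment operation is not
defined by the protocol; subtraction is this package's reading), + 3 mm →
PTV_HR; an elective CTV_EN/PTV_EN; PRV margins of 5 mm (cord) and 3 mm
(brainstem). PET uptake is a smooth tumor profile modulated by a
Gaussian-smoothed random field (heterogeneity amplitude 0.45, smoothing
10 mm), rescaled so the in-target maximum equals `suv_max = 12` — an
uptake contrast typical of FDG-avid head-and-neck primaries — with a
generically unique maximum, which the prescription window requires.
Phases II and III shrink the tumor linearly (factors 0.85 and 0.70,
ordinary mid-treatment regression) and shift the anatomy by 2–4 mm; the
analytic reference→phase displacement (rigid shift plus tumor-centred
contraction with a 40 mm Gaussian falloff) is exposed as the case's
deformation fields. Everything is bit-reproducible from `(config, seed)`.

What the phantom does *not* emulate: realistic CT texture and anatomy,
PET noise and partial-volume effects, registration error (the deformation
fields are exact by construction), delineation uncertainty, and
intra-fraction motion. Passing tests therefore demonstrate the
correctness and internal consistency of the planning and evaluation
chain, not clinical plan quality on real images.

## 10. Problem sizes and numerical defaults

The shipped defaults keep the full pipeline at desk scale: 64³ dose grid,
82 control points over two arcs, ≈ 4600 optimization sample points, 5000
evaluation points, three phases planned and summed in a few minutes on a
single core. Unit tests run the same code on 32³/24³ grids. Key numerical
tolerances: trilinear domain edge 1e−9 voxel, gamma pass margin 1e−9,
optimizer convergence at 1e−4 relative objective change, MU conservation
checked to 1e−9.

## 11. Known limitations

* The dose engine's absolute calibration is arbitrary; only relative
  comparisons within the package are meaningful.
* Per-row avoidance subtraction keeps a single segment per leaf pair;
  genuinely annular BEV topologies are approximated.
* The greedy leaf search explores single-leaf steps; it refines the
  NNLS solution but does not guarantee a global optimum.
* Delivery-time estimates rank plans; they are not predictions of
  measured treatment times.
* The deformation model is analytic and smooth; dose-warping error under
  real, noisy registrations is out of scope.
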