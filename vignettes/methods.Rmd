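---
title: "Methods: morphometry, stain quantification, serum analytics and gated statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry, stain quantification, serum analytics and gated statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of what it computes, the choices
behind the numerics, and what its validation does and does not establish.

## Cardiomyocyte morphometry

### Descriptors

A cross-sectioned cell is a labeled pixel region. From it we compute:

- **area** — pixel count × `pixel_size`², reported in µm² (px² when no
  calibration is supplied, `pixel_size = 1`).
- **aspect** — the major/minor axis ratio of the moment-equivalent
  ellipse, from the eigenvalues of the second central moment matrix of
  the pixel coordinates. Rotation-invariant by construction; 1 for a
  circle.
- **area/box** — area divided by the area of the bounding rectangle
  *aligned with the region's principal axes*. For any ellipse this is
  π/4 ≈ 0.785 regardless of orientation. We deliberately use the
  oriented rather than the axis-aligned box: an axis-aligned box makes
  the descriptor swing by >20% as a 2:1 ellipse rotates through 45°,
  which would let image orientation masquerade as shape change. The
  oriented box keeps area/box a pure shape quantity. Box extents are
  pixel-center projections plus one pixel of width.
- **roundness** — perimeter²/(4π·area); 1 for a circle, growing with
  boundary complexity. The perimeter estimator matters: counting
  boundary-pixel edges overestimates circle perimeters by ~8–10% and
  would bias every CII upward. We instead trace the ordered boundary
  chain (EBImage's contour follower), smooth it with a circular moving
  average whose window adapts to contour length (odd, `round(n/64)`
  clamped to [3, 9]) and take the closed polygon length. The adaptive
  window is what keeps the estimate stable both for small cells and for
  upsampled (staircase) boundaries; with it, circle roundness is within
  ~2% for radii ≥ 30 px and drifts < 2% under 2× nearest-neighbour
  upscaling.
- **radius ratio** — max/min distance from the centroid to the smoothed
  boundary; 1 for a circle, ~a/b for an ellipse.

The **cardiomyocyte irregularity index** is the fixed combination

CII = aspect − area/box + roundness + radius ratio.

Each term is ≥ its circular value except area/box, which enters with a
negative sign and *decreases* with irregularity, so the index increases
monotonically with every descriptor's departure from circularity. The
circle fixed point is 1 − π/4 + 1 + 1 = 3 − π/4 ≈ 2.215, which the test
suite verifies to 3% on rasterized circles of radius 30–60 px (measured
error is ≲ 0.5%; the 3% band absorbs discretization at the small end).

Regions with fewer than 20 pixels are rejected (descriptors are unstable
below that), border-touching regions are excluded by default (a truncated
section has no meaningful shape), and collinear-pixel regions raise an
error naming the region. Masks are the first-class input; the package
does not attempt automatic H&E segmentation — ground-truth masks are the
tested path, mirroring the manual single-cell outlining such studies use.

### Classification and thresholds

The area-versus-CII plane is partitioned by **reference-population
quantile gates** derived from control cells: the normal-size band is
[5th, 95th] percentile of control areas and the irregularity cutoff the
95th percentile of control CII (both configurable). This mirrors
reference-population gating in nuclear morphometric analysis, from which
cell-level morphometry of this kind is adapted. Size and shape gates are
independent, giving six exhaustive, mutually exclusive classes (N, I, HR,
HI, AR, AI). Values exactly on a threshold take the non-extreme side — a
deterministic, measure-zero tie rule.

Two consequences of quantile gating are worth stating plainly:

- Classifying the control population against its own default gates
  necessarily yields ≈ 90% size-normal and ≈ 95% shape-regular cells;
  this is a property of the construction, not a measurement error, and
  the suite asserts it.
- Equivalently, ~14.5% of truly normal cells are relabeled by the
  default gates. Recovery-style validation (how well generated class
  mixtures are recovered end to end) therefore uses wider 1/99/99 gates,
  whose intrinsic ~3-point trim is small against the ±5-point recovery
  tolerance. The defaults remain 5/95/95 for analysis use, where the
  trimmed band *defines* the normal range against which disease groups
  are contrasted.

Per-animal profiles report class percentages (always summing to 100),
mean CII, and **area variability** as the coefficient of variation of
cell area — unitless, hence comparable across animals and calibrations;
the protocol minimum of 50 cells per animal triggers a warning, not an
error, below it.

## Collagen quantification

A picrosirius field is quantified by red-channel dominance:
d = R − (G + B)/2 per pixel, stained ⟺ d > t. By default t is Otsu's
threshold on d, floored at `min_dominance = 0.2`: tissue background sits
near d ≈ 0.1, picrosirius red near d ≈ 0.57, and the floor prevents Otsu
from force-splitting an unstained field into two classes (an all-
background image correctly measures fraction 0). The per-field readout is
the stained **area fraction** (primary; robust to illumination) plus the
mean dominance over stained pixels (intensity, arbitrary units). Animal
scores are the mean and SD over fields, with a warning when the field
count differs from the ten the acquisition protocol prescribes. Published
collagen values in this study family are in arbitrary ImageJ units; the
package reports fractions and makes no attempt to match that scale.

## Serum analytics

Atherogenic ratios are algebraic: CRI-I = TC/HDLc, CRI-II = LDLc/HDLc,
AC = (TC − HDLc)/HDLc, with AC ≡ CRI-I − 1 (asserted to 1e−12) and
invariance under any common rescaling of the inputs (so mg/dL vs mmol/L
is immaterial). HDLc ≤ 0 is a domain error naming the animal.

Relative miRNA expression uses plain 2^−ΔΔCt (no amplification-efficiency
correction): ΔCt = Ct(target) − Ct(spike-in normalizer) per sample;
ΔΔCt subtracts the *arithmetic mean* ΔCt of the reference group per
target (equivalently the geometric mean in fold space — the averaging
rule had to be chosen, and cycle-space arithmetic means are the standard);
fold = 2^−ΔΔCt. Technical replicate wells are averaged at the Ct level
before ΔCt, again the standard practice. Two exact identities follow and
are tested: the geometric mean of reference-group folds is 1, and any
global shift of the normalizer Ct leaves all folds unchanged.

## Gated group statistics

For each variable: Shapiro–Wilk per group (≥ 3 values required per
group); the parametric route (one-way ANOVA, Tukey HSD) is taken only
when **every** group passes at the gate level, otherwise Kruskal–Wallis
with Dunn's rank-based pairwise test (tie-corrected pooled variance,
Holm-adjusted by default; Bonferroni or none are available and recorded).
Groups with constant values — where Shapiro–Wilk is undefined — are
flagged and force the nonparametric route. Summaries follow the route:
mean ± SD, or median with 25th–75th percentiles.

The all-groups-must-pass gate has a knowable routing rate: k Gaussian
groups route parametric with probability 0.95^k (85.7% at k = 3), and
the tests assert that exact expectation rather than a folk figure. The
type-I error of the full gate → omnibus path is checked by simulation
(2000 null replicates, 5 groups × 10) against the 95% binomial band
around 0.05.

Letters come from the insertion–absorption **compact letter display**:
start with all groups in one letter class; for each significant pair,
split every class containing both; absorb subset classes; order classes
by their smallest group index. The defining property — two groups share a
letter ⟺ adjusted p ≥ α — is verified on every output by exhaustive pair
scan (and on random p-matrices in the property tests). Processing groups
in input order makes the display deterministic; it is not guaranteed to
be the globally minimal letter set in pathological cases, which is the
accepted trade-off for determinism.

## The synthetic-data generator

The generator exists because studies of this design publish summary
statistics, not raw per-animal data, so validation must be against
constructed truth.

- **Cells** are noisy ellipses: a base ellipse (elongation e, area A)
  whose radial outline is perturbed by cosine modes 2–5 with 1/k weights
  scaled to a total amplitude (`boundary_noise`). The family is
  star-convex, so rasterization is an exact radial test, and it spans
  the aspect/roundness/radius-ratio space the descriptors measure.
  Default class parameters emulate adult-rat cardiomyocyte
  cross-sections: normal ≈ 300 ± 40 µm², hypertrophic ≈ 600 ± 60,
  atrophic ≈ 120 ± 20; regular outlines at elongation 1.15 ± 0.08 with
  2% boundary noise, irregular at 1.55 ± 0.15 with 14%. The default
  calibration of 0.4 µm/px (typical of 200–400× micrographs) keeps
  normal cells near radius 25 px, where descriptors are stable. Cells
  are placed by dart throwing with a 2 px margin between bounding disks
  (measured cells must be single, non-merging sections), largest first;
  an infeasible density errors with the achieved count.
- **Collagen fields** threshold a smooth random texture at the exact
  quantile of the requested fraction, so the rendered stain share equals
  truth to within one pixel, in colors the default dominance rule
  separates cleanly.
- **Serum panels** draw Gaussian (symmetric) or moment-matched
  log-normal (skewed) values — log-normal being the minimal right-skewed
  family consistent with analytes reported as median (IQR). Scales in
  the bundled study design echo published control-group magnitudes
  (e.g. an adhesion-molecule analyte at 0.14 ± 0.03 ng/mL) purely as
  realism anchors.
- **Ct tables** shift the target Ct of group g by −log₂(fold g) cycles
  against a reference baseline, with configurable Gaussian cycle noise
  on both target and normalizer.

Every generator requires an explicit seed and refuses to run without one;
equal seed means byte-identical output, and the full pipeline
(`run_study_pipeline()`) writes byte-identical CSVs across runs at a
fixed seed.

What the generator does **not** emulate: real H&E/picrosirius texture,
color variation and illumination gradients; segmentation difficulty
(masks are exact); spatial correlation of cell types within a field;
assay-specific noise physics (Luminex, ELISA); amplification-efficiency
differences between targets. Passing recovery tests therefore
demonstrates that the *measurement and inference chain* is correct given
faithful segmentation — not that segmentation of real micrographs is
solved, which is out of scope.

## Problem sizes and runtime choices

The validation suite uses sizes chosen to give stable statistics at
desk-scale runtimes: 1000-cell control populations and 500-cell animals
over 10 seeds for mixture recovery (multinomial SE ≈ 2 points); 10 fields
per fraction for collagen; n = 30 per group for fold recovery; 2000 null
replicates for the type-I check; and a 5-group × 4-animal × 60-cell
default study design in the end-to-end pipeline. These are the package's
own validation conditions; larger runs only narrow the Monte-Carlo error.

## Known limitations

- Descriptor accuracy degrades below ~15 px radius; the 20-pixel floor
  rejects only the unusable extreme. Calibrations coarser than ~0.5 µm/px
  for rat-heart work push atrophic cells toward that regime.
- The automatic threshold-plus-watershed segmentation fallback is not
  provided; the package is mask-driven by design.
- The compact letter display is deterministic but not guaranteed minimal.
- 2^−ΔΔCt assumes ~100% amplification efficiency for all targets;
  efficiency-corrected models are deliberately out of scope.
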