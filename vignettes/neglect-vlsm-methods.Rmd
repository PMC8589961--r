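---
title: "Methods: lesion-symptom mapping of lateralised neglect"
author: "neglectVLSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-symptom mapping of lateralised neglect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neglectVLSM)
```

## The problem

Visuospatial neglect after stroke comes in dissociable lateralised
forms. *Egocentric* neglect is a failure to explore one side of space:
on a cancellation task the patient omits targets on one side of the
page. *Allocentric* neglect is object-centred: the patient cancels
distractor hearts whose gap faces the neglected side, producing
consistently lateralised false positives. Voxel-lesion symptom mapping
(VLSM) asks, voxel by voxel, whether patients with damage at that
location have more severe deficits than patients without, and with a
large enough cohort yields anatomical maps of each deficit's neural
correlates. This package implements that analysis chain — scoring,
voxelwise statistics, and map post-processing — together with a
synthetic-cohort generator that implants a known lesion-deficit
relationship, so the whole chain can be validated against ground truth
without clinical data.

## Behavioural scoring

A standard sheet carries 150 heart outlines on a landscape A4 page: 50
complete targets and 50 left-gap and 50 right-gap distractors. The
scorer (`scoreSheet()`) computes:

* **Centre of cancellation.** Each complete target receives a weight
  linear in its left-right position, `w = (x − x_c)/(W/2)` in [−1, 1]
  where `x_c` is the page centre and `W` the page width; the score is
  the mean weight of the *marked* targets. The linear weighting is the
  simplest scheme consistent with "a numeric weight based on location
  along the right/left axis"; positive values mean marks concentrated
  rightward, i.e. left egocentric neglect. A full marking therefore
  scores the mean weight of all targets — near 0 on a balanced layout —
  and a single mark at the right page edge scores +1.
* **Allocentric proportional score.** Lateralised false positives
  divided by reported targets:
  `(FP_left−gap − FP_right−gap) / (all marked stimuli)`. Counting *all*
  marked stimuli in the denominator (a false positive is itself a
  reported target from the patient's point of view) keeps the score
  bounded in [−1, 1].
* **Categorical labels.** The normative thresholds act on raw count
  asymmetries — right-half hits minus left-half hits (targets exactly at
  the page centre count toward neither half), and left-gap minus
  right-gap false positives. Egocentric asymmetry above +3 (below −3)
  flags left (right) egocentric neglect; allocentric asymmetry above +1
  (below −1) flags left (right) allocentric neglect. All four
  inequalities are strict: boundary values are unimpaired. Labels
  combine freely.
* **Exclusion.** Sheets with fewer than 5 hits are unreliable and are
  flagged excluded, with no labels; with zero marked stimuli the
  continuous scores are undefined (NA).

The continuous scores, not the labels, feed the voxelwise statistics:
binary group membership selects the analysis cohort while the continuous
severity drives the per-voxel test.

Mirror antisymmetry is the key structural property of the scorer:
reflecting every stimulus about the page centre and swapping the gap
sides negates all four lateralised scores and swaps left/right labels.
The test suite enforces it across simulated sheets of every phenotype.

## Lesion pre-processing

Masks are binary volumes on one shared grid; `readMaskSet()` binarizes
at 0.5 and rejects volumes whose shape or affine (beyond 1e-4 mm per
entry) disagrees. `smoothBinarizeZ()` implements the standard
delineation-regularisation step: a 1-D Gaussian along z only, with
`sd = FWHM/(2√(2 ln 2))` converted to voxel units (default FWHM 5 mm),
followed by re-binarization at 0.5. The kernel is truncated at ±4 sd and
renormalized to unit sum (mass loss below 1e-4, deterministic support);
edges replicate the nearest slice so lesions touching the field of view
do not shrink spuriously. Both all-zero and all-one volumes are fixed
points. Lesion volume is voxel count × voxel volume, reported in cm³.

All world-space reasoning goes through the 4×4 voxel-to-world affine
(0-based voxel indices, mm, world x running left→right); grids are
assumed already standardized — spatial normalization of clinical scans
is out of scope.

## The mass-univariate model

For one analysis, `runVlsm()` chains four steps:

1. **Overlap filter.** Only voxels lesioned in at least `minOverlap`
   patients (default 10, inclusive) are tested; the count of included
   voxels is the family size `n_tests`. The filter is applied within
   each analysis cohort, since each lateralised analysis has its own
   sampling space.
2. **Lesion-volume control.** The severity score is residualized on
   total lesion volume by ordinary least squares (`score ~ 1 + volume`)
   before any voxel is tested. This implements "controlled for lesion
   volume" while keeping the per-voxel test a pure two-sample t; it
   makes the t map exactly invariant to adding any multiple of volume
   to the scores (a property the suite checks at 1e-8). A constant
   volume vector is degenerate: scores are mean-centred instead and the
   run manifest records the fallback.
3. **Pooled-variance one-tailed t.** At each voxel the adjusted scores
   split into lesioned and intact groups;
   `t = (m̄₁ − m̄₂)/(s_p √(1/n₁ + 1/n₂))` with the pooled variance on
   `df = n − 2`. The `direction` parameter orients the test so the
   hypothesised lesion-deficit association is positive — left-neglect
   analyses test lesion ⇒ higher score, right-neglect analyses negate
   the score first — because the sign convention of the published
   analyses' toolchain for right-lateralised deficits is not stated,
   the orientation is an explicit per-analysis parameter rather than a
   guess. Voxels where either group has fewer than 2 members are
   untestable: dropped from the map and counted in the manifest. Zero
   pooled variance with equal means yields t = 0.
4. **t→z and Bonferroni.** The one-tailed p comes from the exact t
   upper tail and is mapped through the standard-normal quantile, both
   on the log scale, so the conversion stays accurate for extreme
   statistics and is reproducible at the small n of simulated cohorts
   (a large-df normal approximation would not be). The threshold is
   `z_cut = Φ⁻¹(1 − α/n_tests)`; at the published family size of
   589,216 voxels and α = 0.05 this gives corrected α = 8.49 × 10⁻⁸ and
   z-cut 5.23, which the acceptance suite reproduces from the
   arithmetic alone.

Every run emits a manifest (n_subjects, n_tests, n_untestable, df,
alpha_corrected, z_cut, n_significant, direction, min_overlap) so the
pipeline's headline numbers are traceable. Zero included voxels is a
valid outcome (empty maps, `n_tests = 0`), not an error.

## Map post-processing

* **Overlap** (`mapOverlap()`): common voxel count and percentages of
  each map; empty maps give 0 with an `undefined` flag rather than NaN.
* **Mirror homologue** (`mirrorHomologue()`): each significant voxel is
  reflected through the *world* midsagittal plane x = 0 and assigned to
  the voxel containing the reflected point — not by flipping the first
  array axis, which would be wrong whenever the midline does not fall
  on the central column. On symmetric grids the operation is exact and
  an involution; asymmetric grids fall back to nearest-voxel assignment
  with a warning, and reflections leaving the field of view are dropped
  and counted. Hemisphere membership is the sign of world x; voxel
  centres within half a voxel of x = 0 are "midline" and are excluded
  from homologue comparisons by the compare stage (the mirror itself
  maps them to themselves, preserving the involution).
* **Atlas description** (`atlasFractions()`): winner-take-all integer
  labels; for each ROI intersecting the map it reports the significant
  voxel count and the percentage of the ROI covered, sorted by count
  descending; ROIs without significant voxels are omitted, empty ROIs
  are skipped with a warning, and significant voxels outside every ROI
  are counted separately (so per-ROI counts never sum to more than the
  map total).
* **Peak** (`peakVoxel()`): maximum z and its world coordinate; ties
  break to the lexicographically smallest voxel index and are flagged.

## The synthetic cohort generator

The generator is the test harness: it emulates the *structure* of an
acute-stroke cohort, not any particular clinical sample.

* **Lesions** are thresholded ellipsoidal distance fields: a territory
  seed is sampled by weight (territory seeds stand in for vascular
  territories; seeds near the midline naturally produce
  midline-crossing lesions, which are retained — no special casing), the
  centroid is jittered and snapped to a voxel centre, a radius is drawn
  uniformly from `lesionRadiusRangeMm`, and per-axis scale factors are
  drawn within 1 ± `anisotropyJitter` (default 0.1; 0 gives exact
  spheres, which the geometry tests use because the enclosed-voxel
  count then has a closed form). This is the simplest contiguous-blob
  model with controllable volume; blobs are 6-connected by
  construction at the default radii. Default radii of 5-20 mm on 2 mm
  voxels give volumes of roughly 0.5-30 cm³, the scale reported for
  acute stroke cohorts.
* **Behaviour** follows a linear lesion-deficit model
  `score = β·load + γ·volume + ε`, where `load` is the lesioned
  fraction of the implanted critical region, `γ·volume` is a
  lesion-volume nuisance effect (exercising the residualization), and
  `ε ~ N(0, σ²)`. The published work measured behaviour rather than
  modelling it; this linear form is a harness choice that makes ground
  truth exact, not a claim about the underlying science.
* **Sheets** place 150 stimuli by dart throwing with a 10 mm minimum
  separation on a 297 × 210 mm page, with each stimulus type balanced
  25/25 across the page halves as on the printed sheet — a full marking
  then has exactly zero count asymmetry. Ego phenotypes omit targets
  with probability rising logistically toward the neglected side
  (`P(mark) = 1 − s·logistic(k(c − u))` with steepness k = 20 and cut
  `c = s − 1` in normalized page units), so severity 1 spares
  essentially nothing left of the midline while keeping the sheet
  scorable; allo phenotypes mark neglected-gap distractors with
  probability `0.8·s`. Scored severities are monotone in the severity
  parameter on average, which the suite verifies over 100 sheets per
  level.

Everything is seeded: identical configs reproduce bit-identical cohorts
and sheets, and simulation never perturbs the caller's RNG state.

What the generator does **not** emulate: realistic vascular-territory
shapes, haemorrhage versus ischemia, scan modality or delineation
noise, lesion evolution, or correlated multi-deficit behaviour. Passing
recovery tests therefore demonstrate that the statistical machinery
finds what was implanted under the stated model — not that the pipeline
would reproduce any particular clinical map.

## Study conditions used in the tests

The simulation-based checks run on deliberately small grids so the full
suite stays fast while the statistics remain non-trivial:

* **Null calibration:** 200 cohorts of n = 40 on a 20 × 20 × 10 grid of
  2 mm voxels, β = 0, γ = 0, σ = 1. The fraction of cohorts with any
  Bonferroni-significant voxel must stay within Monte-Carlo slack of
  the nominal 0.05 (observed well below it — Bonferroni over spatially
  correlated lesion columns is conservative).
* **Recovery:** one seeded cohort of n = 60 with a 6 mm spherical
  critical region on one of two territory seeds, radii 4-12 mm, β = 2,
  γ = 0.005, σ = 0.02 — the strong-effect, low-noise regime, chosen
  a priori as a deficit signal an order of magnitude above the noise.
  The significant map must reach Dice ≥ 0.5 against the implanted
  region and the peak z must fall within one voxel of its centroid
  ("within one voxel" meaning the 3 × 3 × 3 neighbourhood: the peak may
  land on a diagonal neighbour when finite lesion sampling makes an
  adjacent voxel marginally better correlated with load). The
  significant cluster is expected to extend slightly beyond the region
  itself — neighbouring voxels are lesioned by the same blobs and so
  carry correlated signal — which is why Dice, not exact equality, is
  the criterion.

## Numerical choices and degenerate inputs

* Gaussian kernel truncation at ±4 sd, renormalized; nearest-edge
  replication along z.
* t→z via exact t tail on the log scale; z is signed, so
  anti-hypothesis effects get negative z and can never pass the cut.
* Peak ties break lexicographically on voxel index (deterministic and
  order-independent).
* Degenerate volume covariate → mean-centring with a warning and a
  manifest flag; untestable voxels → dropped and counted; empty
  inclusion set → empty maps with `n_tests = 0`; zero marked stimuli →
  NA scores and exclusion.
* Sub-seeds for the lesion, behaviour and sheet streams are derived
  from the config seed so the streams are independent but jointly
  reproducible.

## Limitations

The package assumes masks already share one standardized grid —
delineation, reorientation and warping of clinical scans are upstream,
out-of-scope steps. The mass-univariate model tests each voxel
marginally; multivariate or disconnection-based mapping is not
implemented. The Bonferroni correction is deliberately conservative
(specificity over sensitivity); with small cohorts it will miss weak
effects, as the null-calibration results illustrate. Atlas handling is
winner-take-all on integer labels; probabilistic atlases must be
thresholded upstream.
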