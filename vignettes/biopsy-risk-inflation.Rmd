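---
title: "Simulating risk inflation in image-targeted prostate biopsy"
author: "BiopsySim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating risk inflation in image-targeted prostate biopsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiopsySim)
```

## The question being simulated

Biopsy-derived parameters — the maximum cancer core length (MCCL) and the
percentage of positive cores — are widely used to attribute prostate-cancer
risk, with a common rule calling a case *high risk* at ≥6 mm MCCL and/or
≥50% positive cores. These conventions were calibrated on systematic
transrectal ultrasound (TRUS) biopsy, which samples the gland blind to
tumour location. An image-targeted biopsy deliberately oversamples the
lesion, so the same parameters shift upward for the same underlying
disease: *risk inflation*. BiopsySim quantifies that shift by Monte-Carlo
simulation on three-dimensional gland/lesion models: it plans a 12-core
TRUS scheme and transperineal template-targeted schemes (1–5 cores),
perturbs every core by a targeting-error draw, measures per-session MCCL,
% positive cores, detection and risk class, and aggregates over a cohort.

Because the whole-mount prostatectomy reconstructions behind the original
study are not deposited, the package ships a first-class synthetic-cohort
generator that emulates that cohort's published population statistics, and
a reconstruction path (`readContourStack()` → `alignSlices()` →
`interpolateShape()` → `correctShrinkage()`) for user-supplied 5-mm
step-section contour stacks.

## Coordinate conventions

All lengths are millimetres. x is lateral (left–right), y antero-posterior
(anterior positive), z the base–apex axis (base positive). The gland is an
ellipsoid with aspect 1 : 0.75 : 0.9 (a prostate is wider than it is tall,
and slightly shorter base–apex than laterally); the urethra is the line
x = y = 0; the anterior/posterior zone boundary is the urethra-level
coronal plane y = 0. Contour stacks use an axial coordinate that increases
from base toward apex in steps of the slice thickness.

## The synthetic cohort generator

`defaultCohortSpec()` encodes the emulated population; every number below
is a package default stored in the spec object, never hard-coded
downstream.

| Quantity | Model | Calibration anchor |
|---|---|---|
| Gland volume | lognormal(log 50.2, 0.35), truncated to [26.8, 127.7] ml | median 50.2 (range 26.8–127.7) |
| Lesions per gland | 1 + NB(size 4, mu 4.8), truncated at 21 | median 5 (range 1–21) |
| Index lesion volume | lognormal(log 1.215, 0.943), truncated to [0.015, 13.242] ml | median 1.215, mean 1.895 ml |
| Non-index volume | lognormal(log 0.019, 1.710), truncated to [0.001, 1.842] ml | median 0.019, mean 0.082 ml |
| Anterior placement | Bernoulli(415/665) | 415 anterior / 250 posterior lesions |
| Gleason mix | (≤6, 7, ≥8) = (0.57, 0.35, 0.08) per case | cohort percentages |
| False-positive target rate | 0.34 of targeted sessions | reported mpMRI false-positive rate |

The lognormal shape parameters come from the published median/mean ratios
(for a lognormal, mean/median = exp(sdlog²/2)); the negative-binomial size
was chosen so the far tail of ~665 lesion-count draws reaches 21, the
published maximum. Truncation moves the medians by ≲2%, well inside the
10% tolerance the distribution-matching tests use.

**Lesion shape.** Lesions are ellipsoids, rotated only about the base–apex
axis so that every 5-mm cross-section is an exact ellipse (this keeps the
contour-emission path analytic and oracle-checkable). Their aspect is
*oblate*: the axial semi-axis is f × the volume-equivalent radius with
f ~ U(0.4, 0.7), and the in-plane axes share the remaining volume with an
in-plane ratio q ~ U(0.6, 1). This encodes step-section morphology: tumour
foci spread within the transverse plane and are thin along the base–apex
axis, so a sub-0.5 ml focus is typically confined to one 5-mm section and
an index lesion to two to four. An isotropic shape model would give small
lesions 8–12 mm axial chords — exactly the axis transperineal needles
travel — and would overstate targeted MCCL by ~50% relative to the
published pattern. What ellipsoids still cannot represent is the
sparseness and irregularity of real small foci, whose effective
cross-section for a needle is far below that of a convex body of equal
volume; consequences are discussed under *Limitations*.

**Containment.** Lesions are placed by rejection sampling (up to 200
attempts at three progressively sphere-blended aspects), requiring 26
surface probe points to lie within the capsule with 0.5 mm tolerance. So
that placement always terminates, the index volume is additionally capped
at 30% of the gland volume; a degenerate spec whose index range lies
entirely above the cap is rejected as infeasible. The largest placed
lesion is relabelled as the index.

**False-positive targets.** A 34% imaging false-positive rate is modelled
as benign-target models appended to the cohort: with n targetable cancer
models, m = round(r/(1−r) · n) glands are added whose only "lesion" is a
benign region ≥0.2 ml flagged `isFalseTarget` — it attracts targeted cores
but contributes zero cancer length. The published arithmetic (107 glands
"resulting in" 141 at a 34% rate) is not recoverable from any simple
formula, so the rate and the cohort size are controlled independently;
with r = 1 every generated model is a benign-target model, the only cohort
for which *every* targeted session samples benign tissue.

## Reconstruction from step-section contours

`alignSlices()` translates each slice in-plane so capsule centroids
chain-align to the midgland reference, defined (the source protocol does
not define it) as the slice of maximal capsule area; translation-only
registration is used, with rotation left as an extension point.
`interpolateShape()` is shape-based interpolation in the classical
signed-distance sense: per slice and structure a signed distance field
(positive inside) is computed on a common grid, linearly interpolated
along z, and thresholded at zero, so the original polygons are recovered
at their own slice positions to within one voxel. Beyond a structure's
terminal contours the field is extended by phantom slices carrying
(end SDF − slice thickness), closing the shape with a ~45° cap over one
slice; on an analytically sliced 10 mm sphere the end-cap overshoot and
the interior linear-interpolation undershoot nearly cancel, and the
reconstructed volume is within a fraction of a percent of 4π r³/3 (the
test band is 5%). The default voxel spacing is 0.5 mm — below the lesion
scale at desk-scale memory; halving it changes reconstructed volumes by a
decreasing amount (a convergence trend the tests check).

`correctShrinkage()` reverses fixation shrinkage by scaling coordinates
about the model origin by the linear factor 1.10, assumed isotropic;
volumes scale by exactly 1.10³ = 1.331. Because the factor is isotropic
the order relative to interpolation is immaterial for volumes; it is
applied after reconstruction, which also fixes the coordinate convention.
Factors below 1 are permitted (with a warning) so the operation is
invertible in round-trip tests.

## Core geometry

A biopsy core is a zero-width segment of effective (sampling-notch)
length 17 mm — a typical 18-gauge device; the value is configurable and
recorded in every output because MCCL saturates at it. The cancer length
of a core is the length of its segment intersected with the **union** of
the true lesions: per-lesion chords come from the quadratic along the ray
in the lesion frame, clipped to the segment, and overlapping intervals are
merged so abutting foci are not double-counted. Both the total
within-union length (primary) and the longest contiguous run are
reported — 5-mm histology cannot resolve contiguity, so the total is the
defensible default. Positivity is any intersection (threshold 0 mm,
configurable for sensitivity analyses).

Against voxel models the same quantity is integrated by sampling the
segment at half-voxel steps and trilinearly interpolating the mask
occupancy; a binarised mask localises each surface crossing only to about
half a voxel, so agreement with the analytic path is distributional —
median deviation ~0.1 mm at 0.5 mm spacing, grazing-ray worst cases up to
~2 voxels — and the tests assert it at that granularity.

## Biopsy schemes

**TRUS 12-core.** The source material gives the construction concept
(coordinates from the anus centre and gland centre, aligned to the
base–apex axis, blinded to pathology) but no coordinates, so the scheme is
parametric: left/right × base/mid/apex × medial/lateral, with planned
midpoints at fractions of the gland semi-axes (x ±0.25 medial / ±0.65
lateral, y −0.5 — the posterior peripheral zone where systematic cores are
taken — and z ±0.5), trajectories fanning from an anus reference 25 mm
posterior and 40 mm beyond the apex, and per-repetition Gaussian jitter
(SD 1.5 mm per axis) standing in for probe/needle insertion variability,
whose magnitude is not published. The plan reads only anatomy; a test
verifies invariance under permuting or deleting lesions.

**Template-targeted.** A 5-mm brachytherapy template anchors the urethra
at grid D 2.0, i.e. grid position (D, 2.0) maps to x = y = 0, with
needles along +z. For the imaged target (the largest lesion ≥0.2 ml —
multi-lesion allocation is an extension point; for a false-positive
target, the benign region's own geometry), each lattice position is scored
by its maximal chord through the target with the effective segment centred
on that chord ("aiming for the deepest part"), and the k distinct
positions with the longest chords are taken. Because per-core lengths at
distinct positions are independent, this greedy choice equals the
exhaustive lattice optimum — verified against an independent exhaustive
search for k ≤ 2. Ties break by distance to the target centroid, then
lexicographic grid order; if fewer positions intersect the target than
cores requested, the remainder stack on the best position with a warning.

## The targeting-error model

Errors have zero-mean normal components in three orthogonal directions,
displacing the core midpoint only (pure translation; needle bending is out
of scope). Two published statements are in tension: a deflection SD of
"3 mm in any direction" and a registration SD of 3 mm add to 9 + 9 mm²
only *per direction*, yet the "set total variance" of 25 mm² exceeding
that additive 18 mm² can be read either per direction (per-axis SD 5 mm)
or summed over the three axes (per-axis SD 5/√3 ≈ 2.89 mm). The package
default is the **summed** reading: one combined displacement with
per-axis variance 25/3, so the sampled per-axis variances sum to exactly
the set total — the error-model contract the acceptance checks verify.
The alternative is one option away
(`errorModel(varianceAccounting = "per_axis")`), and matters: under the
summed reading a targeted core's transverse miss SD (2.89 mm) is small
against even a 0.2–0.5 ml lesion's in-plane radius (4.5–6.3 mm), making
per-core hit probabilities 0.7–0.9; the per-axis reading roughly halves
them and moves the simulated targeted MCCL/% positive much closer to the
published pattern. A `"components"` mode samples deflection and
registration separately (registration applied to targeted cores only by
default — it is an image-fusion error; `applyRegistrationTo = "all"` is
available) and rescales their sum to the set total, keeping the components
inspectable.

## The Monte-Carlo engine and seeding

`runStrategy()` performs the repetitions for one model and strategy: TRUS
plans are re-drawn each repetition (anatomic jitter — whether the original
re-randomised positions per repetition is unstated; re-drawing represents
true operator variability), targeted plans are fixed at planning time with
error applied at realization, and every core in every repetition gets an
independent error draw. Each (model, strategy) pair runs on its own
deterministic substream derived from the master seed, so subsets can be
re-run bit-identically. `errorSweep()` re-runs strategies across a range
of total errors (default 1–10 mm) and reports cohort-averaged all-cancer
sensitivity.

## Risk metrics and statistics

Per repetition: MCCL = max core cancer length, % positive = 100 ×
positive/deployed cores, detection = ≥1 positive core, and the risk class
from the inclusive rule (≥6 mm and/or ≥50%). Sensitivity averages
per-repetition detection over the cancer-bearing models of a stratum — a
"detected in ≥1 of 500 repetitions" rule would saturate at 1 and is not
used — excluding benign-target models from the denominator and models with
no eligible target (which revert to TRUS-only analysis) from targeted
strategies. Note that folding benign-target sessions *into* the average
instead multiplies targeted sensitivities by ≈0.66 at the default
false-positive rate; published headline sensitivities appear to be of that
folded kind. Case-level risk aggregates the repetitions by majority rule
(high if >0.5 of repetitions are high; the per-case proportions are always
returned so any other rule can be applied post hoc). Cohort summaries
report mean ± SD, median and 90th percentile (inclusive
linear-interpolation convention, `quantile` type 7) of per-case means,
per stratum (all / significant / insignificant) and strategy; clinical
significance is any true lesion ≥0.5 ml and/or Gleason ≥7, both inclusive.
`compareStrategies()` pairs per-case means by model and reports the paired
Student t test plus two readings of a "paired Kolmogorov–Smirnov test"
(the named variant is nonstandard): a two-sample KS on the matched value
sets and a KS of the paired differences against their sign-flipped mirror.
p-values are raw; no multiplicity correction is applied.

## Problem sizes used by the tests

The shipped tests run the full pipeline at the emulated cohort size (107
glands) with 100 repetitions per strategy, the error sweep on 30 glands at
200 repetitions over {1, 5, 10} mm, and distribution matching on 1,000
draws — sizes chosen to keep the whole suite in the minutes range on one
CPU while leaving Monte-Carlo noise well below the effects being asserted.
The repetition default in `defaultRunConfig()` remains 500.

## Limitations

* Ellipsoid lesions understate the irregularity and sparseness of real
  small foci. Under the default (summed) error reading this matters most
  in the insignificant stratum: simulated targeted cores hit 0.2–0.5 ml
  convex lesions often enough that the ≥50%-positive-cores leg of the risk
  rule fires in a majority of repetitions, so — unlike the published
  finding — insignificant cases are not uniformly low risk, and the
  acceptance suite records that divergence honestly rather than papering
  over it. Passing the synthetic-cohort tests therefore demonstrates the
  machinery and the directional effects, not real-data magnitudes in that
  stratum.
* mpMRI appearance, reader variability and lesion conspicuity are not
  modelled; the false-positive rate enters only as benign-target sessions.
* Intra-lesion Gleason pattern is not mapped (non-index lesions are
  assigned grade ≤6); Gleason upgrade dynamics are out of scope.
* Needles are straight, zero-width segments; tissue deformation,
  pubic-arch interference and probe pressure are not modelled.
* Histology-to-in-vivo registration is translation-plus-isotropic-scaling
  only.

## A worked example

```{r example, eval = FALSE}
spec <- defaultCohortSpec(nProstates = 107)
cohort <- buildCohort(spec)
res <- runCohort(cohort, c("TRUS12", "TARGETED_3", "TARGETED_4"),
                 em = errorModel(), reps = 100, seed = 1)
summarizeCohort(res, cohort)
compareStrategies(res[res$strategy == "TRUS12", ],
                  res[res$strategy == "TARGETED_4", ], metric = "mccl")
```
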