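---
title: "Measuring enhancing tumor volume from T1 subtraction MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring enhancing tumor volume from T1 subtraction MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliovol)
```

## The measurement problem

Response assessment of enhancing brain tumors is usually done with diameter
rules: RECIST takes the longest in-plane diameter of the lesion, the Macdonald
criteria the product of the longest diameter and its perpendicular. Around a
surgical resection cavity both break down: residual tumor sits in a thin,
irregular enhancing rim around a cavity whose shape changes over time, so a
collapsing cavity *shrinks* every diameter while the rim of viable tumor may
be *growing*. Intrinsically T1-bright material such as subacute blood inside
the cavity adds a second failure mode: it looks like enhancement on a
post-contrast scan but is equally bright without contrast.

`gliovol` implements a nearly automated volumetric alternative that needs only
the standard T1-weighted pre- and post-contrast series plus two gross hand
outlines, and quantifies specifically *enhancing* tissue:

1. **Fusion.** The pre-contrast volume is rigidly registered onto the
   post-contrast grid and resampled there, removing pose and
   slice-acquisition differences.
2. **Subtraction.** The voxelwise map `post − pre` isolates signal that
   appeared after contrast (plus a global brightness offset).
3. **Brightness normalization.** MRI pixel values are not standardized, so the
   *mode* of the subtraction values inside a user-drawn normal-parenchyma
   region (away from vessels, ventricles and CSF) is taken as a correction
   factor and subtracted from all tumor and mucosa values. The mode, rather
   than the mean, is used because it is insensitive to the few contaminated
   voxels a gross outline inevitably contains.
4. **Per-scan threshold.** The nasal mucosa enhances strongly and reliably in
   essentially every patient, so it serves as an internal calibration: the
   mucosa region is located automatically by registering a packaged atlas
   template to the patient's post-contrast scan and propagating its mucosa
   label (a manual mucosa outline may override this). From the corrected
   mucosa values the top 5% (by voxel count) are trimmed to guard against
   outliers, and the enhancement cut-off is 25% of the remaining maximum.
5. **Counting.** Voxels in the gross tumor region whose corrected subtraction
   value exceeds the cut-off are counted; the count times the voxel volume is
   the enhancing tumor volume in cm³.

Because the correction factor absorbs any additive brightness change and the
threshold rescales with any multiplicative one, the enhancement mask is
invariant to global additive offsets on either scan and equivariant under
joint positive scaling — the properties the test suite verifies exactly.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `thresholdFraction` | 0.25 | – | fraction of the trimmed mucosa maximum used as cut-off; 0.40 is the common alternative. Larger values can only shrink the measured volume. |
| `exclusionFraction` | 0.05 | – | top fraction of corrected mucosa values trimmed before taking the maximum, as an order-statistic trim over voxels (`k = ceiling(f·n)` values removed). |
| `binWidth` | 1 | intensity | histogram bin width of the mode estimator; 1 suits integer-valued MRI data. Bins are centered on integer multiples of the width, ties break toward the lowest bin. |
| `strictGreater` | `TRUE` | – | `>` versus `>=` at the cut-off. Either reading of "above the threshold" is defensible; strict `>` is the default and the choice is recorded in every report. |
| `registration$searchRange` | 8 | mm | half-width of the deterministic coarse translation search that initializes the optimizer. |

## Registration choices

Pre/post pairs of the same patient differ by pose, a global brightness change,
and a sparse set of enhancing voxels, so a 6-degree-of-freedom rigid model is
the minimal adequate one; no deformable step is attempted. The similarity
objective is negative normalized cross-correlation over the in-field overlap:
it is invariant to global linear intensity changes — exactly the nuisance in a
same-subject, same-modality pair — and, with trilinear interpolation, is
piecewise smooth in the transform parameters, which the derivative-free
Nelder–Mead optimizer requires (a hard-binned mutual-information histogram is
locally flat and stalls the simplex). Optimization is multi-resolution
(decimation by 4, 2, 1) with a deterministic grid search over translations and
per-axis rotations at the coarsest level; there is no randomness, so repeated
runs return identical transforms.

Two numerical decisions matter downstream:

* **Identity snapping.** A recovered transform smaller than 0.1 mm / 0.1° in
  every component is snapped to the exact identity, and identity resampling on
  an identical grid returns the input array untouched. Sub-voxel "motion" of
  that size is below the method's resolution, and snapping avoids spreading
  interpolation blur through an already-aligned pair — this is what makes the
  noiseless phantom recovery exact rather than merely close.
* **Atlas mapping is affine** (9 DOF: pose + per-axis scale), since a
  template's head size need not match the patient's. The propagated label is
  mapped with nearest-neighbour interpolation so it stays binary.

Masks always travel by nearest-neighbour; intensity images by trilinear
interpolation. Voxels that leave the field of view become `NA` and are
excluded from every statistic.

## What the phantom emulates — and what it does not

The synthetic generator (`phantomSpec()`, `phantomScenario()`) builds a head
ellipsoid of uniform parenchyma (400 intensity units) containing a dark
resection cavity, an enhancing rim shell of configurable thickness
(+100 units post-contrast by default), optional cavity "blood" added to both
scans (or, as a counterfactual, to the post scan only), a thin meningeal arc
on the head surface (+80), a nasal-mucosa slab in inferior slices (+160, so
the default threshold lands at 40, comfortably between parenchyma noise and
rim contrast), a global post-scan brightness offset (+7 by default, varying
across serial timepoints), and Rician noise synthesized from two independent
Gaussian channels — the magnitude-image noise statistics of MRI. The study
noise condition is σ = 2, i.e. 2% of the rim contrast. All randomness flows
from one integer seed; the noiseless `post − pre` difference equals the
specified contrast map exactly, which is what makes every voxel's truth known.

Canned scenarios mirror the situations the method must handle: a baseline rim;
a cavity that collapses while its rim thickens (diameters fall, true volume
rises); subacute blood; a meningeal rim with both a narrow and a generous
gross outline; and an eight-timepoint serial series with a prescribed
non-monotonic rim-volume trajectory, per-timepoint pose shifts of ±2 mm and
varying brightness offsets. In the serial scenario the gross tumor outline is
fixed at the baseline (semi-axes cavity + 6.5 mm) so that, as in practice, the
*same* transferred outline contains the rim at every timepoint.

The phantom is deliberately geometric. It does not emulate bias fields,
partial-volume fading at rim edges, vessels or choroid plexus inside the
outline, patient-to-patient anatomy for the atlas (the shipped atlas is the
phantom's own template — a real clinical atlas is a pluggable asset), or
deformable brain shift. Passing tests therefore demonstrate the algorithm's
arithmetic, invariances and registration behaviour under controlled
conditions; they are not evidence about segmentation accuracy on clinical
images.

## Degenerate inputs and tie-breaks

* Normal region smaller than 100 valid voxels: error (warning below 1000).
* Tumor and normal outlines overlapping: error — the correction must come
  from uninvolved tissue. A detected mucosa region intersecting the tumor
  outline is likewise a hard error.
* Mucosa with no net enhancement after correction (trimmed maximum ≤ 0):
  error, since no threshold can be calibrated.
* Mode ties: the lowest bin center wins, making the estimate deterministic.
* Zero enhancing voxels is a *valid result*, not an error.
* Negative corrected values are retained unclamped; they never exceed a
  positive threshold.
* DICOM series with a missing slice or inconsistent spacing/orientation are
  rejected with the gap named; scanner rescale slope/intercept is applied,
  nothing else.

## Conventional measurements

For side-by-side comparison the package also measures lesion masks the
conventional way: the RECIST longest diameter is the maximum pairwise distance
between in-mask voxel centers on the slice where it is largest (computed on
the convex hull; verified against an O(n²) oracle), and the Macdonald
perpendicular diameter is the extent of that slice's centers projected onto
the orthogonal direction — a deterministic reading of "widest perpendicular
width". Diameters span the full lesion extent including the enclosed cavity,
as calipers would. Products are reported to 3 significant figures. Response
*categorization* (PR/SD/PD rules, steroid criteria, RANO) is deliberately out
of scope.

## Problem sizes used by the tests

The suite and the acceptance script run on 64 × 64 × 44 voxel phantoms at
1 mm isotropic spacing — large enough for three resolution levels in the
registration and several-thousand-voxel rims, small enough that the full
suite, including twenty reseeded noise phantoms and three eight-timepoint
serial analyses, completes in minutes. Registration accuracy at this size is
about 0.1–0.25 mm / 0.25°, an order of magnitude inside the 0.5 mm / 0.5°
acceptance band.

## Known limitations

Non-enhancing tumor is invisible to the method by construction. Rigid fusion
cannot follow true brain shift between serial scans. The atlas mechanism is
only as good as the template supplied. And the measurement inherits every
caveat of enhancement itself: steroids, radiation necrosis, pseudoprogression
and anti-angiogenic therapy all change enhancement without changing tumor
burden; interpreting the numbers remains a clinical task.
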